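test_that("protein grouping has the requested size and is seeded", {
  ids <- paste0("p", 1:10)
  g <- assign_grouping(ids, heldout_fraction = 0.3, seed = 4)
  expect_equal(sum(g$group == "heldout"), 3)
  expect_identical(g, assign_grouping(ids, heldout_fraction = 0.3, seed = 4))
  expect_error(assign_grouping(ids, heldout_fraction = 0.01, seed = 1), "empty")
  expect_error(assign_grouping("p1", 0.5, 1), "at least 2")
})

test_that("pairs classify into C1/C2/C3 by held-out membership", {
  g <- tibble::tibble(
    id = c("p1", "p2", "p3", "p4"),
    group = c("train", "train", "heldout", "heldout")
  )
  pairs <- tibble::tibble(
    id_a = c("p1", "p1", "p3", "p1", "p3"),
    id_b = c("p2", "p3", "p4", "p1", "p3")
  )
  out <- classify_pairs(pairs, g)
  expect_equal(as.character(out$split), c("C1", "C2", "C3", "C1", "C3"))
  expect_error(
    classify_pairs(tibble::tibble(id_a = "p9", id_b = "p1"), g),
    "p9"
  )
})

test_that("a degenerate all-train grouping sends every pair to C1", {
  g <- tibble::tibble(id = paste0("p", 1:6), group = "train")
  pairs <- tibble::tibble(
    id_a = paste0("p", 1:5), id_b = paste0("p", 2:6), label = 1L
  )
  out <- classify_pairs(pairs, g)
  expect_true(all(out$split == "C1"))
})

test_that("benchmark split satisfies the membership invariants exactly", {
  # brute-force membership check on a 50-protein world
  world <- synthetic_world(n_proteins = 50, n_positives = 30, seed = 9)
  pairs <- sample_labeled_pairs(world, n_positives = 30, ratio = 4, seed = 9)
  split <- build_split(
    pairs[pairs$label == 1, ], pairs[pairs$label == 0, ],
    heldout_fraction = 0.4, ratio = 3, seed = 2
  )
  train <- split$grouping$id[split$grouping$group == "train"]
  held <- split$grouping$id[split$grouping$group == "heldout"]

  for (k in seq_len(nrow(split$c1))) {
    expect_true(split$c1$id_a[k] %in% train && split$c1$id_b[k] %in% train)
  }
  for (k in seq_len(nrow(split$c2))) {
    expect_equal(
      (split$c2$id_a[k] %in% held) + (split$c2$id_b[k] %in% held), 1
    )
  }
  for (k in seq_len(nrow(split$c3))) {
    expect_true(split$c3$id_a[k] %in% held && split$c3$id_b[k] %in% held)
  }
  # no C3 protein occurs in any C1 pair (leakage check)
  c1_prot <- unique(c(split$c1$id_a, split$c1$id_b))
  c3_prot <- unique(c(split$c3$id_a, split$c3$id_b))
  expect_length(intersect(c1_prot, c3_prot), 0)

  # strata are disjoint and drawn from the input pairs
  keys <- function(tb) paste(tb$id_a, tb$id_b)
  all_keys <- c(keys(split$c1), keys(split$c2), keys(split$c3))
  expect_false(any(duplicated(all_keys)))
  expect_true(all(all_keys %in% keys(pairs)))
  # positives are never discarded
  expect_equal(
    sum(split$c1$label) + sum(split$c2$label) + sum(split$c3$label),
    sum(pairs$label)
  )
})

test_that("each stratum keeps the exact configured class ratio", {
  world <- synthetic_world(n_proteins = 80, n_positives = 60, seed = 12)
  pairs <- sample_labeled_pairs(world, n_positives = 60, ratio = 6, seed = 12)
  split <- build_split(
    pairs[pairs$label == 1, ], pairs[pairs$label == 0, ],
    heldout_fraction = 0.32, ratio = 4, seed = 3
  )
  for (s in list(split$c1, split$c2, split$c3)) {
    expect_equal(sum(s$label == 0), 4 * sum(s$label == 1))
  }
  # determinism of the full split under the seed
  split2 <- build_split(
    pairs[pairs$label == 1, ], pairs[pairs$label == 0, ],
    heldout_fraction = 0.32, ratio = 4, seed = 3
  )
  expect_identical(
    split[c("c1", "c2", "c3", "grouping")],
    split2[c("c1", "c2", "c3", "grouping")]
  )
  # shortfall is reported per stratum
  expect_error(
    build_split(
      pairs[pairs$label == 1, ], pairs[pairs$label == 0, ][1:60, ],
      heldout_fraction = 0.32, ratio = 6, seed = 3
    ),
    "shortfall"
  )
})

test_that("expected stratum shares follow the binomial expectation", {
  # with held-out fraction f, a uniformly random pair lands in C1/C2/C3
  # with probabilities (1-f)^2, 2f(1-f), f^2
  f <- 0.32
  ids <- sprintf("p%03d", 1:200)
  withr::with_seed(31, {
    pairs <- tibble::tibble(
      id_a = sample(ids, 3000, replace = TRUE),
      id_b = sample(ids, 3000, replace = TRUE)
    )
    pairs <- pairs[pairs$id_a != pairs$id_b, ]
  })
  shares <- sapply(1:30, function(seed) {
    g <- assign_grouping(ids, heldout_fraction = f, seed = seed)
    out <- classify_pairs(pairs, g)
    as.numeric(table(out$split) / nrow(out))
  })
  avg <- rowMeans(shares)
  expect_equal(avg[1], (1 - f)^2, tolerance = 0.02)
  expect_equal(avg[2], 2 * f * (1 - f), tolerance = 0.02)
  expect_equal(avg[3], f^2, tolerance = 0.03)
})
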