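# A shared small separable problem: pair features from a strong-signal world.
make_training_problem <- function(n_proteins = 60, n_pos = 40, ratio = 4,
                                  seed = 2) {
  world <- synthetic_world(
    n_proteins = n_proteins, n_positives = n_pos,
    ratio = ratio, signal = 12, noise_sd = 0.02, seed = seed
  )
  pairs <- sample_labeled_pairs(world, n_positives = n_pos, ratio = ratio, seed = seed)
  list(
    x = pair_features(pairs, world$embeddings),
    y = pairs$label,
    pairs = pairs,
    world = world
  )
}

small_cfg <- function(...) {
  mlp_config(hidden_sizes = c(64, 16), epochs = 40, ...)
}

test_that("the MLP separates a strong-signal world", {
  prob <- make_training_problem()
  n <- nrow(prob$x)
  withr::with_seed(1, idx <- sample.int(n, round(0.7 * n)))
  model <- train_mlp(prob$x[idx, ], prob$y[idx], small_cfg(seed = 3))
  s <- pairppi:::model_scores(model, prob$x[-idx, ])
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(score_curves(prob$y[-idx], s)$auroc, 0.95)
})

test_that("MLP training is deterministic under its seed", {
  prob <- make_training_problem(n_proteins = 40, n_pos = 20)
  m1 <- train_mlp(prob$x, prob$y, small_cfg(seed = 7))
  m2 <- train_mlp(prob$x, prob$y, small_cfg(seed = 7))
  expect_identical(m1$weights, m2$weights)
  expect_identical(
    pairppi:::model_scores(m1, prob$x),
    pairppi:::model_scores(m2, prob$x)
  )
})

test_that("training rejects single-class and malformed inputs", {
  prob <- make_training_problem(n_proteins = 40, n_pos = 20)
  expect_error(
    train_mlp(prob$x, rep(1, nrow(prob$x)), small_cfg()),
    "both classes"
  )
  expect_error(train_rf(prob$x, rep(0, nrow(prob$x))), "both classes")
  expect_error(
    train_mlp(prob$x, prob$y[-1], small_cfg()),
    "matching lengths"
  )
  model <- train_mlp(prob$x, prob$y, small_cfg())
  expect_error(
    pairppi:::model_scores(model, prob$x[, 1:5]),
    "input dimension"
  )
})

test_that("MLP training loss is non-increasing on a memorizable problem", {
  withr::with_seed(6, {
    x <- matrix(rnorm(20 * 4), 20, 4)
    y <- as.integer(x[, 1] > 0)
  })
  colnames(x) <- paste0("f", 1:4)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  # full-batch training so the epoch loss is the exact objective
  cfg <- mlp_config(
    hidden_sizes = c(16, 8), epochs = 60, batch_size = 32, seed = 2
  )
  model <- train_mlp(x, y, cfg)
  diffs <- diff(model$loss_history)
  expect_true(all(diffs <= 1e-4))
  expect_lt(
    model$loss_history[length(model$loss_history)], model$loss_history[1]
  )
})

test_that("prediction scores are order-invariant and in range", {
  prob <- make_training_problem(n_proteins = 40, n_pos = 25)
  feats <- prob$world$embeddings
  for (head in c("mlp", "rf", "svm")) {
    model <- train_ppi_model(
      prob$pairs, feats,
      head = head, config = small_cfg(seed = 4), seed = 4
    )
    test_pairs <- utils::head(prob$pairs, 20)
    swapped <- tibble::tibble(
      id_a = test_pairs$id_b, id_b = test_pairs$id_a,
      label = test_pairs$label
    )
    p1 <- predict(model, test_pairs, feats)
    p2 <- predict(model, swapped, feats)
    expect_equal(p1$score, p2$score, info = head)
    expect_true(all(p1$score >= 0 & p1$score <= 1), info = head)
  }
})

test_that("empty pair lists yield empty score lists", {
  prob <- make_training_problem(n_proteins = 40, n_pos = 20)
  model <- train_mlp(prob$x, prob$y, small_cfg())
  expect_length(pairppi:::model_scores(model, prob$x[0, , drop = FALSE]), 0)
})

test_that("score thresholding uses the inclusive >= rule", {
  expect_equal(classify_scores(c(0.5, 0.499, 1), 0.5), c(1L, 0L, 1L))
  expect_equal(classify_scores(rep(1, 4)), rep(1L, 4))
})

test_that("the RF head separates the strong-signal world and is seeded", {
  prob <- make_training_problem()
  n <- nrow(prob$x)
  withr::with_seed(2, idx <- sample.int(n, round(0.7 * n)))
  m1 <- train_rf(prob$x[idx, ], prob$y[idx], seed = 5)
  s1 <- pairppi:::model_scores(m1, prob$x[-idx, ])
  expect_gt(score_curves(prob$y[-idx], s1)$auroc, 0.9)
  m2 <- train_rf(prob$x[idx, ], prob$y[idx], seed = 5)
  expect_identical(s1, pairppi:::model_scores(m2, prob$x[-idx, ]))
})

test_that("the SVM head produces calibrated probabilities", {
  prob <- make_training_problem(n_proteins = 40, n_pos = 25)
  model <- train_svm(prob$x, prob$y, seed = 1)
  s <- pairppi:::model_scores(model, prob$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(score_curves(prob$y, s)$auroc, 0.8)
})

test_that("a zero-signal world yields chance-level held-out AUROC", {
  aurocs <- sapply(1:3, function(seed) {
    world <- synthetic_world(
      n_proteins = 80, n_positives = 60, ratio = 4,
      signal = 0, seed = seed
    )
    pairs <- sample_labeled_pairs(world, n_positives = 60, ratio = 4, seed = seed)
    n <- nrow(pairs)
    withr::with_seed(seed, idx <- sample.int(n, round(0.7 * n)))
    model <- train_ppi_model(
      pairs[idx, ], world$embeddings,
      head = "rf", seed = seed
    )
    pred <- predict(model, pairs[-idx, ], world$embeddings)
    score_curves(pred$label, pred$score)$auroc
  })
  expect_gt(mean(aurocs), 0.38)
  expect_lt(mean(aurocs), 0.62)
})
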