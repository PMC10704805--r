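#' Assign proteins to train / held-out groups
#'
#' Draws a uniformly random held-out protein set of size
#' `round(heldout_fraction * n)`, reproducibly under `seed`. The grouping is
#' the basis of the C1/C2/C3 pair-input partition: pairs with both proteins
#' in the train group form C1, pairs with exactly one held-out protein form
#' C2, and pairs with both proteins held out form C3.
#'
#' @param protein_ids Character vector of protein identifiers (deduplicated
#'   internally).
#' @param heldout_fraction Fraction of proteins to hold out, in (0, 1)
#'   (default 0.32; see Details).
#' @param seed Integer seed.
#' @details The default `heldout_fraction = 0.32` makes the expected positive
#'   pair shares of C1/C2/C3 approximately 46% / 44% / 10%, matching the
#'   benchmark design this package reproduces.
#' @return A tibble `id`, `group` (`"train"` or `"heldout"`), with the
#'   fraction and seed stored as attributes.
#' @export
assign_grouping <- function(protein_ids, heldout_fraction = 0.32, seed = 1L) {
  ids <- sort(unique(as.character(protein_ids)))
  n <- length(ids)
  if (n < 2) {
    abort("Need at least 2 proteins to form a grouping.")
  }
  if (!is.numeric(heldout_fraction) || heldout_fraction <= 0 || heldout_fraction >= 1) {
    abort("`heldout_fraction` must be in (0, 1).")
  }
  n_held <- round(heldout_fraction * n)
  if (n_held == 0 || n_held == n) {
    abort(sprintf(
      "heldout_fraction = %g on %d proteins yields an empty %s set.",
      heldout_fraction, n, if (n_held == 0) "held-out" else "train"
    ))
  }
  held <- withr::with_seed(seed, sample(ids, n_held))
  out <- tibble(
    id = ids,
    group = ifelse(ids %in% held, "heldout", "train")
  )
  attr(out, "heldout_fraction") <- heldout_fraction
  attr(out, "seed") <- seed
  out
}

#' Classify labeled pairs into C1/C2/C3 strata
#'
#' Adds a `split` column: `"C1"` when both proteins are in the train group,
#' `"C2"` when exactly one is held out, `"C3"` when both are held out. A
#' self-pair (A, A) is C1 if A is a train protein and C3 otherwise.
#'
#' @param pairs Pair tibble (`id_a`, `id_b`, ...).
#' @param grouping Tibble from [assign_grouping()].
#' @return `pairs` with an added `split` factor column.
#' @export
classify_pairs <- function(pairs, grouping) {
  assert_pair_table(pairs)
  ga <- grouping$group[match(pairs$id_a, grouping$id)]
  gb <- grouping$group[match(pairs$id_b, grouping$id)]
  bad <- unique(c(pairs$id_a[is.na(ga)], pairs$id_b[is.na(gb)]))
  if (length(bad) > 0) {
    abort(sprintf(
      "Protein(s) not assigned in grouping: %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  n_held <- (ga == "heldout") + (gb == "heldout")
  pairs$split <- factor(c("C1", "C2", "C3")[n_held + 1L], levels = c("C1", "C2", "C3"))
  as_tibble(pairs)
}

#' Build a C1/C2/C3 benchmark split
#'
#' Draws one protein grouping over every protein occurring in the labeled
#' pairs, classifies each pair into C1 (train), C2, or C3, and then
#' down-samples negatives within each stratum (uniformly, seeded) so that
#' every stratum has exactly `ratio` negatives per positive. Positives are
#' never discarded.
#'
#' @param positives,negatives Pair tibbles with labels 1 and 0 respectively.
#' @param heldout_fraction Fraction of proteins held out (default 0.32).
#' @param ratio Enforced negatives-per-positive ratio within each stratum
#'   (default 10).
#' @param seed Integer seed driving both the grouping and the down-sampling.
#' @return A `benchmark_split` object: a list with pair tibbles `c1`, `c2`,
#'   `c3` (columns `id_a`, `id_b`, `label`), the `grouping` tibble, and the
#'   parameters used.
#' @export
build_split <- function(positives, negatives, heldout_fraction = 0.32,
                        ratio = 10, seed = 1L) {
  assert_pair_table(positives, "positives")
  assert_pair_table(negatives, "negatives")
  positives <- canonicalize_pair_cols(positives)
  negatives <- canonicalize_pair_cols(negatives)
  positives$label <- 1L
  negatives$label <- 0L
  all_pairs <- bind_rows(positives, negatives)
  grouping <- assign_grouping(
    unique(c(all_pairs$id_a, all_pairs$id_b)),
    heldout_fraction = heldout_fraction, seed = seed
  )
  all_pairs <- classify_pairs(all_pairs, grouping)

  take <- function(split_name, sub_seed) {
    sub <- all_pairs[all_pairs$split == split_name, , drop = FALSE]
    pos <- sub[sub$label == 1L, , drop = FALSE]
    neg <- sub[sub$label == 0L, , drop = FALSE]
    want <- ratio * nrow(pos)
    if (nrow(neg) < want) {
      abort(sprintf(
        "%s has %d positives but only %d negatives (need %d, shortfall %d).",
        split_name, nrow(pos), nrow(neg), want, want - nrow(neg)
      ))
    }
    keep <- withr::with_seed(sub_seed, sample.int(nrow(neg), want))
    out <- bind_rows(pos, neg[sort(keep), , drop = FALSE])
    out$split <- NULL
    as_tibble(out)
  }
  res <- structure(
    list(
      c1 = take("C1", seed + 1L),
      c2 = take("C2", seed + 2L),
      c3 = take("C3", seed + 3L),
      grouping = grouping,
      heldout_fraction = heldout_fraction,
      ratio = ratio,
      seed = seed
    ),
    class = "benchmark_split"
  )
  res
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat("C1/C2/C3 benchmark split (heldout_fraction =", x$heldout_fraction,
      ", ratio = 1:", x$ratio, ", seed =", x$seed, ")\n", sep = "")
  for (s in c("c1", "c2", "c3")) {
    p <- sum(x[[s]]$label == 1L)
    cat(sprintf(
      "  %s: %d pairs (%d positive, %d negative)\n",
      toupper(s), nrow(x[[s]]), p, nrow(x[[s]]) - p
    ))
  }
  invisible(x)
}

#' @describeIn build_split one row per stratum with pair and protein counts.
#' @param x A `benchmark_split` object.
#' @param ... Unused.
#' @export
tidy.benchmark_split <- function(x, ...) {
  purrr::map2(c("C1", "C2", "C3"), list(x$c1, x$c2, x$c3), function(nm, tb) {
    tibble(
      split = nm,
      n_pairs = nrow(tb),
      n_positive = sum(tb$label == 1L),
      n_negative = sum(tb$label == 0L),
      n_proteins = length(unique(c(tb$id_a, tb$id_b)))
    )
  }) |> bind_rows()
}

#' @describeIn build_split stacked bar chart of stratum sizes by label.
#' @param object A `benchmark_split` object.
#' @export
autoplot.benchmark_split <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("n_positive", "n_negative"),
      names_to = "class", values_to = "n"
    ) |>
    mutate(class = ifelse(.data$class == "n_positive", "positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$split, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "pairs",
      title = "Benchmark split composition"
    ) +
    ggplot2::theme_minimal()
}

#' Write / read the pieces of a benchmark split
#'
#' Writes `c1.tsv`, `c2.tsv`, `c3.tsv` (pair TSVs) and `grouping.tsv`
#' (protein id, group) plus a small `manifest.tsv` holding the fraction,
#' ratio and seed, into `dir`.
#'
#' @param split A `benchmark_split` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "benchmark_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs(split$c1, file.path(dir, "c1.tsv"))
  write_pairs(split$c2, file.path(dir, "c2.tsv"))
  write_pairs(split$c3, file.path(dir, "c3.tsv"))
  readr::write_tsv(split$grouping, file.path(dir, "grouping.tsv"))
  readr::write_tsv(
    tibble(
      heldout_fraction = split$heldout_fraction,
      ratio = split$ratio, seed = split$seed
    ),
    file.path(dir, "manifest.tsv")
  )
  invisible(dir)
}
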