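#' Run the full pair-input benchmark pipeline
#'
#' End-to-end driver: partitions a labeled pair set into the C1/C2/C3
#' benchmark strata, trains a classifier head on most of C1, and evaluates it
#' on a held-back portion of C1 and on the two independent test strata. The
#' C1 hold-back (a stratified 20% by default) gives a within-distribution
#' reference point, so the C1 >= C2 >= C3 difficulty ordering of the
#' pair-input problem can be read off one run.
#'
#' @param pairs Labeled pair tibble (`id_a`, `id_b`, `label`).
#' @param features An `embedding_table` covering every protein in `pairs`.
#' @param heldout_fraction Protein hold-out fraction for the split
#'   (default 0.32).
#' @param ratio Enforced negatives-per-positive ratio per stratum
#'   (default 10).
#' @param head Classifier head: `"mlp"` (default), `"rf"` or `"svm"`.
#' @param config [mlp_config()] for the MLP head.
#' @param c1_eval_fraction Fraction of C1 (stratified by label) held back
#'   from training for within-C1 evaluation (default 0.2; 0 trains on all of
#'   C1 and skips the within-C1 evaluation).
#' @param seed Integer seed driving the split, the C1 hold-back and the
#'   model head.
#' @return A `ppi_benchmark` object: list with the `split`
#'   (a `benchmark_split`), the trained `model`, and `evaluations` — a named
#'   list of [evaluate_predictions()] reports for `c1` (held-back part),
#'   `c2` and `c3`.
#' @export
run_ppi_benchmark <- function(pairs, features,
                              heldout_fraction = 0.32,
                              ratio = 10,
                              head = c("mlp", "rf", "svm"),
                              config = mlp_config(),
                              c1_eval_fraction = 0.2,
                              seed = 1L) {
  head <- match.arg(head)
  positives <- pairs[pairs$label == 1L, , drop = FALSE]
  negatives <- pairs[pairs$label == 0L, , drop = FALSE]
  split <- build_split(positives, negatives,
    heldout_fraction = heldout_fraction, ratio = ratio, seed = seed
  )

  c1 <- split$c1
  if (c1_eval_fraction > 0) {
    pos_idx <- which(c1$label == 1L)
    neg_idx <- which(c1$label == 0L)
    withr::with_seed(seed + 17L, {
      hold <- c(
        sample(pos_idx, max(1L, round(c1_eval_fraction * length(pos_idx)))),
        sample(neg_idx, max(1L, round(c1_eval_fraction * length(neg_idx))))
      )
    })
    c1_train <- c1[-hold, , drop = FALSE]
    c1_eval <- c1[hold, , drop = FALSE]
  } else {
    c1_train <- c1
    c1_eval <- NULL
  }

  if (head == "mlp") {
    config$seed <- as.integer(seed)
  }
  model <- train_ppi_model(c1_train, features,
    head = head, config = config, seed = seed
  )

  eval_on <- function(tb) {
    if (is.null(tb) || nrow(tb) == 0) {
      return(NULL)
    }
    pred <- predict(model, tb, features)
    evaluate_predictions(pred$label, pred$score)
  }
  structure(
    list(
      split = split,
      model = model,
      c1_train = c1_train,
      evaluations = list(
        c1 = eval_on(c1_eval),
        c2 = eval_on(split$c2),
        c3 = eval_on(split$c3)
      ),
      seed = seed,
      head = head
    ),
    class = "ppi_benchmark"
  )
}

#' @export
print.ppi_benchmark <- function(x, ...) {
  cat(sprintf("Pair-input PPI benchmark run (head = %s, seed = %d)\n", x$head, x$seed))
  for (nm in names(x$evaluations)) {
    ev <- x$evaluations[[nm]]
    if (is.null(ev)) next
    cat(sprintf(
      "  %s: AUPR %.4f | AUROC %.4f (prevalence %.4f)\n",
      toupper(nm), ev$aupr, ev$auroc, ev$curves$prevalence
    ))
  }
  invisible(x)
}

#' @describeIn run_ppi_benchmark one row per evaluated stratum with all
#'   scalar metrics.
#' @param x A `ppi_benchmark` object.
#' @param ... Unused.
#' @export
tidy.ppi_benchmark <- function(x, ...) {
  rows <- purrr::imap(x$evaluations, function(ev, nm) {
    if (is.null(ev)) {
      return(NULL)
    }
    dplyr::bind_cols(tibble(split = toupper(nm)), glance(ev))
  })
  bind_rows(rows)
}
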