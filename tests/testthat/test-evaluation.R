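test_that("confusion counts follow the >= decision rule", {
  expect_equal(
    confusion_counts(c(1, 0), c(0.9, 0.1), 0.5),
    tibble::tibble(tp = 1L, tn = 1L, fp = 0L, fn = 0L),
    ignore_attr = TRUE
  )
  expect_equal(
    confusion_counts(c(1, 0), c(0.1, 0.9), 0.5)[c("fn", "fp")],
    tibble::tibble(fn = 1L, fp = 1L),
    ignore_attr = TRUE
  )
  # scores exactly at the threshold are predicted positive
  cc <- confusion_counts(c(1, 0, 1), rep(0.5, 3), 0.5)
  expect_equal(cc$tp + cc$fp, 3)
  expect_error(confusion_counts(c(1, 0), 0.5), "same length")
})

test_that("confusion counts agree with a looping oracle", {
  withr::with_seed(19, {
    for (k in 1:10) {
      n <- sample(5:40, 1)
      labels <- rbinom(n, 1, 0.4)
      scores <- round(runif(n), 2)
      t <- runif(1)
      got <- confusion_counts(labels, scores, t)
      want <- oracle_confusion(labels, scores, t)
      expect_equal(as.list(got), want, ignore_attr = TRUE)
    }
  })
})

test_that("threshold metrics evaluate their defining equations", {
  m <- classification_metrics(list(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(m$mcc, 0)
  expect_equal(m$accuracy, 0.5)

  m <- classification_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(
    unlist(m[c("accuracy", "specificity", "precision", "recall", "mcc")]),
    rep(1, 5),
    ignore_attr = TRUE
  )

  # published-table consistency: counts reconstructed from recall/precision
  # reproduce the printed accuracy and MCC
  cc <- reconstruct_confusion(0.557, 0.902, 806, 8060)
  expect_equal(as.list(cc), list(tp = 449, tn = 8011, fp = 49, fn = 357),
    ignore_attr = TRUE
  )
  m <- classification_metrics(cc)
  expect_equal(m$mcc, 0.688, tolerance = 5e-4)
  expect_equal(m$accuracy, 0.954, tolerance = 5e-4)
})

test_that("zero-denominator metrics are undefined, not zero", {
  # no predicted positives: precision undefined
  m <- classification_metrics(list(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$mcc))
  expect_false(is.na(m$accuracy))
  # all one class: specificity undefined
  m <- classification_metrics(list(tp = 5, tn = 0, fp = 0, fn = 0))
  expect_true(is.na(m$specificity))
})

test_that("MCC matches its formula and symmetries on random instances", {
  withr::with_seed(23, {
    for (k in 1:15) {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      scores <- runif(n)
      t <- 0.5
      cc <- confusion_counts(labels, scores, t)
      m <- classification_metrics(cc)
      want <- oracle_mcc(cc$tp, cc$tn, cc$fp, cc$fn)
      expect_equal(m$mcc, want)
      # invariance under swapping TP<->TN and FP<->FN
      m_swap <- classification_metrics(
        list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
      )
      expect_equal(m_swap$mcc, m$mcc)
      # antisymmetry under label flip (same predictions, flipped truth)
      m_flip <- classification_metrics(
        list(tp = cc$fp, tn = cc$fn, fp = cc$tp, fn = cc$tn)
      )
      if (!is.na(m$mcc) && !is.na(m_flip$mcc)) {
        expect_equal(m_flip$mcc, -m$mcc)
      }
    }
  })
})

test_that("confusion reconstruction follows the rounding recipe", {
  cc <- reconstruct_confusion(0.589, 0.901, 3404, 34040)
  expect_equal(as.list(cc), list(tp = 2005, tn = 33820, fp = 220, fn = 1399),
    ignore_attr = TRUE
  )
  cc <- reconstruct_confusion(1.0, 1.0, 10, 100)
  expect_equal(as.list(cc), list(tp = 10, tn = 100, fp = 0, fn = 0),
    ignore_attr = TRUE
  )
  expect_error(reconstruct_confusion(0.5, 0.01, 10, 3), "Infeasible")
})

test_that("curves hit the degenerate-case values", {
  # perfectly separating scores
  curves <- score_curves(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(curves$auroc, 1)
  expect_equal(curves$aupr, 1)
  # uninformative constant scores
  curves <- score_curves(c(1, 0, 0, 0), rep(0.5, 4))
  expect_equal(curves$auroc, 0.5)
  expect_equal(curves$aupr, 0.25) # prevalence
  expect_error(score_curves(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("AUROC equals the exhaustive Mann-Whitney count", {
  withr::with_seed(29, {
    for (k in 1:12) {
      n <- sample(6:30, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.4)) # force both classes
      scores <- round(runif(n), 1) # coarse grid to exercise ties
      expect_equal(
        score_curves(labels, scores)$auroc,
        oracle_auroc(labels, scores)
      )
    }
  })
})

test_that("curve tibbles are monotone in their sweep", {
  withr::with_seed(33, {
    labels <- rbinom(60, 1, 0.3)
    labels[1:2] <- c(0, 1)
    scores <- runif(60)
  })
  curves <- score_curves(labels, scores)
  expect_true(all(diff(curves$roc$fpr) >= 0))
  expect_true(all(diff(curves$roc$tpr) >= 0))
  expect_true(all(diff(curves$pr$recall) >= 0))
  expect_true(all(diff(curves$pr$threshold) <= 0))
})

test_that("the full evaluation report is internally consistent", {
  withr::with_seed(37, {
    labels <- rbinom(80, 1, 0.25)
    labels[1:2] <- c(0, 1)
    scores <- plogis(rnorm(80) + 2 * labels)
  })
  rep <- evaluate_predictions(labels, scores, threshold = 0.5)
  expect_equal(
    rep$counts$tp + rep$counts$tn + rep$counts$fp + rep$counts$fn,
    length(labels)
  )
  g <- glance(rep)
  expect_true(all(c("accuracy", "mcc", "aupr", "auroc") %in% names(g)))
  td <- tidy(rep)
  expect_equal(
    td$value[td$metric == "auroc"], score_curves(labels, scores)$auroc
  )
})

test_that("curve and split plots build without error", {
  withr::with_seed(41, {
    labels <- rbinom(40, 1, 0.3)
    labels[1:2] <- c(0, 1)
    scores <- runif(40)
  })
  curves <- score_curves(labels, scores)
  expect_s3_class(autoplot(curves, "pr"), "ggplot")
  expect_s3_class(autoplot(curves, "roc"), "ggplot")
})
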