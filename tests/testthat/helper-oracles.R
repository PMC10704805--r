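# Independent oracles used to cross-check package computations.
# These are deliberately naive (loops, full enumeration) and share no code
# with the implementation.

# Needleman-Wunsch global alignment with affine gaps (Gotoh), match +1,
# mismatch 0, gap of length k costing open + k * ext. Returns identity =
# identical aligned positions / alignment length, via explicit traceback.
oracle_global_identity <- function(a, b, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- as.numeric(A[i - 1] == B[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  # traceback counting matches and alignment columns
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1
  j <- m + 1
  matches <- 0
  cols <- 0
  tol <- 1e-9
  while (i > 1 || j > 1) {
    cols <- cols + 1
    if (state == 1) {
      s <- as.numeric(A[i - 1] == B[j - 1])
      matches <- matches + s
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which(abs(prev + s - M[i, j]) < tol)[1]
      i <- i - 1
      j <- j - 1
    } else if (state == 2) {
      if (abs(M[i - 1, j] - open - ext - X[i, j]) < tol) {
        state <- 1
      }
      i <- i - 1
    } else {
      if (abs(M[i, j - 1] - open - ext - Y[i, j]) < tol) {
        state <- 1
      }
      j <- j - 1
    }
  }
  matches / cols
}

# AUROC as the normalized Mann-Whitney U statistic: the fraction of
# (positive, negative) score pairs ranked concordantly, ties counting 1/2.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Confusion counts by explicit looping over examples.
oracle_confusion <- function(labels, scores, threshold) {
  tp <- tn <- fp <- fn <- 0
  for (k in seq_along(labels)) {
    pred <- scores[k] >= threshold
    if (pred && labels[k] == 1) tp <- tp + 1
    if (pred && labels[k] == 0) fp <- fp + 1
    if (!pred && labels[k] == 1) fn <- fn + 1
    if (!pred && labels[k] == 0) tn <- tn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# MCC straight from its formula on scalar counts.
oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) {
    return(NA_real_)
  }
  (tp * tn - fp * fn) / den
}

# Random amino-acid sequence over the standard alphabet.
random_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}

# A small labeled evidence tibble builder used across ingest tests.
make_evidence <- function(id_a, id_b, type, miscore) {
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    interaction_type = type, miscore = miscore
  )
}
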