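#' Global-alignment sequence identity between two protein sequences
#'
#' Computes pairwise sequence identity under a Needleman-Wunsch global
#' alignment with a simple explicit scoring scheme: match +1, mismatch 0,
#' affine gaps (opening -10, extension -0.5 per gapped position; a gap of
#' length k costs 10 + 0.5k). Identity is the number of identical aligned
#' positions divided by the alignment length (gapped columns included), so it
#' lies in \[0, 1\] and is symmetric in its arguments.
#'
#' @param a,b Nonempty amino-acid strings.
#' @return A single number in \[0, 1\].
#' @examples
#' pairwise_identity("ACDE", "ACDE") # 1
#' pairwise_identity("AAAA", "CCCC") # 0
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("Both sequences must be nonempty.")
  }
  a <- toupper(a)
  b <- toupper(b)
  letters_ab <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sm <- diag(1, length(letters_ab))
  dimnames(sm) <- list(letters_ab, letters_ab)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pat == sub & pat != "-") / length(pat)
}

#' Build the negative-sampling candidate pool
#'
#' Applies the three sequential filters that define the eligible-protein pool
#' for negative sampling:
#'
#' 1. proteins occurring in any positive pair are removed;
#' 2. remaining proteins sharing identity `>= identity_cutoff` with any
#'    positive-set protein are removed;
#' 3. the remainder is redundancy-reduced greedily at the same cutoff:
#'    proteins are visited in decreasing sequence-length order (ties broken
#'    by id) and kept unless they reach the cutoff against an already-kept
#'    protein.
#'
#' Identity is computed with [pairwise_identity()].
#'
#' @param proteins A tibble with columns `id`, `sequence` (the full protein
#'   list, e.g. from [read_fasta()]).
#' @param positives A positive pair tibble (`id_a`, `id_b`).
#' @param identity_cutoff Identity fraction at or above which a protein is
#'   filtered (default 0.40).
#' @return A tibble of surviving proteins (`id`, `sequence`).
#' @export
build_candidate_pool <- function(proteins, positives, identity_cutoff = 0.40) {
  if (!is.numeric(identity_cutoff) || identity_cutoff <= 0 || identity_cutoff > 1) {
    abort("`identity_cutoff` must be in (0, 1].")
  }
  assert_pair_table(positives, "positives")
  pos_ids <- unique(c(positives$id_a, positives$id_b))
  missing <- setdiff(pos_ids, proteins$id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Positive-set protein(s) absent from `proteins`: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  pos_seqs <- proteins$sequence[match(pos_ids, proteins$id)]

  # (1) drop positive-set proteins
  pool <- proteins[!(proteins$id %in% pos_ids), , drop = FALSE]
  if (nrow(pool) == 0) {
    return(as_tibble(pool))
  }
  # (2) drop pool proteins homologous to any positive-set protein
  hits_positive <- map_lgl(pool$sequence, function(s) {
    any(map_dbl(pos_seqs, pairwise_identity, b = s) >= identity_cutoff)
  })
  pool <- pool[!hits_positive, , drop = FALSE]
  # (3) greedy intra-pool redundancy reduction, longest first
  ord <- order(-nchar(pool$sequence), pool$id)
  pool <- pool[ord, , drop = FALSE]
  kept <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    redundant <- FALSE
    for (j in which(kept)) {
      if (pairwise_identity(pool$sequence[j], pool$sequence[i]) >= identity_cutoff) {
        redundant <- TRUE
        break
      }
    }
    kept[i] <- !redundant
  }
  out <- pool[kept, , drop = FALSE]
  as_tibble(out[order(out$id), , drop = FALSE])
}

#' Sample non-interacting protein pairs
#'
#' Draws exactly `ratio * nrow(positives)` unordered protein pairs, labeled
#' `0`, uniformly without replacement from the pairing universe formed by the
#' eligible proteins together with the positive-set proteins. Positive pairs
#' and self-pairs are excluded; the draw is reproducible under `seed`.
#'
#' @param positives Positive pair tibble (`id_a`, `id_b`, label 1).
#' @param eligible_ids Character vector of candidate-pool protein ids (e.g.
#'   `build_candidate_pool(...)$id`).
#' @param ratio Negatives per positive (default 10).
#' @param seed Integer seed driving the sampling.
#' @return A tibble `id_a`, `id_b`, `label = 0L` with `ratio * nrow(positives)`
#'   rows, canonicalized, duplicate-free, disjoint from `positives`.
#' @export
sample_negatives <- function(positives, eligible_ids, ratio = 10, seed = 1L) {
  if (!is.numeric(ratio) || ratio < 1 || ratio != round(ratio)) {
    abort("`ratio` must be a positive integer.")
  }
  assert_pair_table(positives, "positives")
  positives <- canonicalize_pair_cols(positives)
  universe <- sort(unique(c(
    as.character(eligible_ids),
    positives$id_a, positives$id_b
  )))
  n <- length(universe)
  n_needed <- as.numeric(ratio) * nrow(positives)
  total_pairs <- n * (n - 1) / 2
  # self-pairs are never sampled, so only non-self positives shrink the space
  nonself <- positives$id_a != positives$id_b
  available <- total_pairs -
    length(unique(pair_key(positives$id_a[nonself], positives$id_b[nonself])))
  if (available < n_needed) {
    abort(sprintf(
      "Pool too small: %d distinct non-positive pairs available, %d requested (shortfall %d).",
      as.integer(available), as.integer(n_needed),
      as.integer(n_needed - available)
    ))
  }
  idx_a <- match(positives$id_a, universe)
  idx_b <- match(positives$id_b, universe)
  pos_num <- (pmin(idx_a, idx_b) - 1) * n + pmax(idx_a, idx_b)

  if (total_pairs <= 5e6) {
    # enumerate the unordered-pair space and sample without replacement
    i <- rep.int(seq_len(n - 1), times = (n - 1):1)
    j <- sequence((n - 1):1, from = 2:n)
    keys <- (i - 1) * n + j
    ok <- which(!(keys %in% pos_num))
    pick <- ok[withr::with_seed(seed, sample.int(length(ok), n_needed))]
    i <- i[pick]
    j <- j[pick]
  } else {
    # rejection sampling: draw in rounds, deduplicate, keep draw order
    i <- integer(0)
    j <- integer(0)
    withr::with_seed(seed, {
      seen <- numeric(0)
      while (length(i) < n_needed) {
        m <- ceiling((n_needed - length(i)) * 1.3) + 100
        ca <- sample.int(n, m, replace = TRUE)
        cb <- sample.int(n, m, replace = TRUE)
        keep <- ca != cb
        lo <- pmin(ca[keep], cb[keep])
        hi <- pmax(ca[keep], cb[keep])
        key <- (lo - 1) * n + hi
        fresh <- !(key %in% seen) & !(key %in% pos_num) & !duplicated(key)
        i <- c(i, lo[fresh])
        j <- c(j, hi[fresh])
        seen <- c(seen, key[fresh])
      }
    })
    i <- i[seq_len(n_needed)]
    j <- j[seq_len(n_needed)]
  }
  tibble(id_a = universe[i], id_b = universe[j], label = 0L)
}
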