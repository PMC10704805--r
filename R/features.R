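AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Amino-acid composition (AAC) of a protein sequence
#'
#' Encodes a sequence as the 20 per-residue frequencies over the standard
#' amino-acid alphabet in alphabetical one-letter order
#' (`ACDEFGHIKLMNPQRSTVWY`). Non-standard residues (e.g. `X`) are excluded
#' from both numerator and denominator, so the vector sums to 1 whenever at
#' least one standard residue is present.
#'
#' @param sequence Nonempty amino-acid string.
#' @return A named numeric vector of length 20.
#' @examples
#' aac("AAAC") # A = 0.75, C = 0.25
#' @export
aac <- function(sequence) {
  chars <- prep_residues(sequence)
  std <- chars[chars %in% AA_STANDARD]
  if (length(std) == 0) {
    abort("Sequence contains no standard amino-acid residues.")
  }
  counts <- table(factor(std, levels = AA_STANDARD))
  out <- as.numeric(counts) / length(std)
  names(out) <- AA_STANDARD
  out
}

#' Dipeptide composition (DPC) of a protein sequence
#'
#' Encodes a sequence as the 400 overlapping-dipeptide frequencies, ordered
#' row-major over the alphabetical amino-acid alphabet (AA, AC, ..., YY).
#' Only dipeptides whose both residues are standard count; the denominator is
#' the number of such valid dipeptides (`L - 1` when the whole sequence is
#' standard), so the vector sums to 1 for all-standard sequences.
#'
#' @param sequence Amino-acid string of length >= 2.
#' @return A named numeric vector of length 400.
#' @examples
#' dpc("ACAC") # AC = 2/3, CA = 1/3
#' @export
dpc <- function(sequence) {
  chars <- prep_residues(sequence)
  if (length(chars) < 2) {
    abort("DPC requires a sequence of length >= 2.")
  }
  first <- chars[-length(chars)]
  second <- chars[-1]
  valid <- first %in% AA_STANDARD & second %in% AA_STANDARD
  if (!any(valid)) {
    abort("Sequence contains no dipeptide of standard residues.")
  }
  dip <- paste0(first[valid], second[valid])
  lv <- as.vector(t(outer(AA_STANDARD, AA_STANDARD, paste0)))
  counts <- table(factor(dip, levels = lv))
  out <- as.numeric(counts) / sum(valid)
  names(out) <- lv
  out
}

prep_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single nonempty string.")
  }
  if (grepl("\\s", sequence)) {
    abort("`sequence` must not contain whitespace.")
  }
  strsplit(toupper(sequence), "")[[1]]
}

#' Mean-pool a per-residue representation matrix
#'
#' Collapses an `L x D` per-residue matrix (one row per residue, e.g. the
#' final-layer hidden states of a protein language model) into a single
#' `D`-dimensional per-protein vector by averaging over the residue axis.
#'
#' @param residue_matrix Numeric matrix with `L >= 1` rows.
#' @return Numeric vector of length `ncol(residue_matrix)`.
#' @examples
#' mean_pool(rbind(c(1, 2), c(3, 4))) # c(2, 3)
#' @export
mean_pool <- function(residue_matrix) {
  if (!is.matrix(residue_matrix) || nrow(residue_matrix) < 1 ||
    ncol(residue_matrix) < 1) {
    abort("`residue_matrix` must be a matrix with at least one row and column.")
  }
  colMeans(residue_matrix)
}

#' Construct an embedding table
#'
#' An embedding table maps protein identifiers to dense per-protein feature
#' vectors of one shared dimensionality. It is the common currency of every
#' feature source in the package: loaded language-model embeddings
#' ([load_embeddings()]) and sequence encoders ([encode_proteins()]) both
#' produce one.
#'
#' @param entries Numeric matrix, one row per protein, with unique non-empty
#'   rownames (the protein ids); all values finite.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(entries) {
  if (!is.matrix(entries) || !is.numeric(entries)) {
    abort("`entries` must be a numeric matrix.")
  }
  ids <- rownames(entries)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("`entries` must have nonempty rownames (protein ids).")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate protein id(s): %s", paste(dup, collapse = ", ")))
  }
  bad <- rowSums(!is.finite(entries)) > 0
  if (any(bad)) {
    abort(sprintf(
      "Non-finite embedding value(s) for id(s): %s",
      paste(head(ids[bad], 5), collapse = ", ")
    ))
  }
  structure(entries, class = c("embedding_table", "matrix", "array"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf(
    "Embedding table: %d proteins x %d dimensions\n", nrow(x), ncol(x)
  ))
  invisible(x)
}

#' @rdname embedding_table
#' @param x An object.
#' @export
embedding_dim <- function(x) {
  stopifnot(inherits(x, "embedding_table"))
  ncol(x)
}

#' Load / save a keyed per-protein embedding table
#'
#' The on-disk format is a headerless TSV keyed-vector dialect: each line is
#' a protein id followed by D tab-separated floats. All vectors must share
#' one dimensionality; ids must be unique; values must be finite.
#'
#' @param path File path.
#' @param expected_dim Optional integer; loading errors if the file's
#'   dimensionality differs.
#' @return [load_embeddings()] returns an `embedding_table`;
#'   [write_embeddings()] invisibly returns the table.
#' @export
load_embeddings <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Embedding file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("Embedding file is empty.")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- map_chr(fields, 1)
  dims <- lengths(fields) - 1L
  if (any(dims < 1)) {
    abort(sprintf(
      "No vector values for id(s): %s",
      paste(head(ids[dims < 1], 5), collapse = ", ")
    ))
  }
  if (length(unique(dims)) > 1) {
    ref <- dims[1]
    off <- ids[dims != ref]
    abort(sprintf(
      "Ragged vector lengths (first is %d): offending id(s) %s",
      ref, paste(head(off, 5), collapse = ", ")
    ))
  }
  d <- dims[1]
  if (!is.null(expected_dim) && d != expected_dim) {
    abort(sprintf(
      "Embedding dimensionality is %d, expected %d.", d, expected_dim
    ))
  }
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1]), numeric(d))
  )
  m <- if (d == 1) matrix(vals, ncol = 1) else t(vals)
  rownames(m) <- ids
  embedding_table(m)
}

#' @rdname load_embeddings
#' @param table An `embedding_table`.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(table)
}

#' Encode proteins with a sequence-composition feature source
#'
#' Applies [aac()] or [dpc()] to every protein and collects the vectors into
#' an [embedding_table()], so composition encoders and loaded language-model
#' embeddings are interchangeable downstream.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param encoder `"aac"` (20-dim) or `"dpc"` (400-dim).
#' @return An `embedding_table`.
#' @export
encode_proteins <- function(proteins, encoder = c("aac", "dpc")) {
  encoder <- match.arg(encoder)
  f <- switch(encoder, aac = aac, dpc = dpc)
  m <- t(vapply(proteins$sequence, f, numeric(if (encoder == "aac") 20 else 400)))
  rownames(m) <- proteins$id
  embedding_table(m)
}

#' Symmetric pair features via the Hadamard product
#'
#' Represents each protein pair as the elementwise (Hadamard) product of the
#' two member feature vectors. The product is symmetric, so the pair
#' representation carries no member-order bias.
#'
#' @param pairs Pair tibble (`id_a`, `id_b`, ...).
#' @param features An `embedding_table` resolving every protein in `pairs`.
#' @return A numeric matrix, one row per pair (in row order of `pairs`),
#'   `embedding_dim(features)` columns.
#' @export
pair_features <- function(pairs, features) {
  assert_pair_table(pairs)
  stopifnot(inherits(features, "embedding_table"))
  ids <- rownames(features)
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), ids)
  if (length(missing) > 0) {
    abort(sprintf(
      "Protein id(s) missing from the feature source: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  m <- unclass(features)[pairs$id_a, , drop = FALSE] *
    unclass(features)[pairs$id_b, , drop = FALSE]
  rownames(m) <- NULL
  # stable column names so tree/kernel backends can match train and test
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}
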