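#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records. The identifier is the
#' header token up to the first whitespace; sequences are uppercased. Standard
#' line-wrapped FASTA is supported.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `sequence` (character,
#'   uppercase amino acids; unknown residues may appear as `"X"`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDE", "FGHI", ">p2", "mkln"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf(
      "Empty sequence for FASTA entr%s: %s",
      if (sum(empty) > 1) "ies" else "y",
      paste(names(set)[empty], collapse = ", ")
    ))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Read protein interaction evidence from a tab-separated file
#'
#' Reads interaction evidence lines carrying two interactor identifiers, an
#' interaction-type term, and a confidence string. Two dialects are supported:
#'
#' * `"minimal"`: exactly four tab-separated columns
#'   (`id_a`, `id_b`, `interaction_type`, `confidence`);
#' * `"mitab"`: full PSI-MI TAB 2.7 records, from which the same four fields
#'   are taken by column index (1, 2, 12, 15). Database prefixes on the
#'   identifiers (e.g. `uniprotkb:`) are stripped, and the human-readable
#'   interaction-type term is extracted from its parenthesized form.
#'
#' The confidence score is taken from an `intact-miscore:<float>` token in the
#' confidence column; rows without a parseable score get `miscore = 0`.
#' Malformed lines (too few columns) are skipped with a warning naming the
#' line number.
#'
#' @param path Path to a tab-separated evidence file.
#' @param format Either `"minimal"` (default) or `"mitab"`.
#' @return A tibble with columns `id_a`, `id_b`, `interaction_type`
#'   (character) and `miscore` (numeric in \[0, 1\]).
#' @export
read_evidence <- function(path, format = c("minimal", "mitab")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Evidence file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  # MITAB files conventionally start with a '#' header line
  is_comment <- startsWith(lines, "#")
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(
      id_a = character(), id_b = character(),
      interaction_type = character(), miscore = numeric()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  min_cols <- if (format == "minimal") 4L else 15L
  ok <- lengths(fields) >= min_cols
  if (any(!ok)) {
    warn(sprintf(
      "Skipping %d malformed evidence line(s) (fewer than %d columns): line(s) %s",
      sum(!ok), min_cols,
      paste(keep[!ok], collapse = ", ")
    ))
  }
  fields <- fields[ok]
  if (length(fields) == 0) {
    return(tibble(
      id_a = character(), id_b = character(),
      interaction_type = character(), miscore = numeric()
    ))
  }
  if (format == "minimal") {
    id_a <- map_chr(fields, 1)
    id_b <- map_chr(fields, 2)
    type <- map_chr(fields, 3)
    conf <- map_chr(fields, 4)
  } else {
    id_a <- strip_db_prefix(map_chr(fields, 1))
    id_b <- strip_db_prefix(map_chr(fields, 2))
    type <- map_chr(fields, 12)
    conf <- map_chr(fields, 15)
  }
  tibble(
    id_a = id_a,
    id_b = id_b,
    interaction_type = type,
    miscore = parse_miscore(conf)
  )
}

# "uniprotkb:P12345" -> "P12345"; identifiers without a prefix pass through
strip_db_prefix <- function(x) {
  sub("^[A-Za-z0-9_.-]+:", "", x)
}

parse_miscore <- function(conf) {
  m <- regmatches(conf, regexpr("intact-miscore:[0-9.eE+-]+", conf))
  out <- numeric(length(conf))
  hit <- grepl("intact-miscore:", conf, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(sub("^intact-miscore:", "", m)))
  out[hit] <- ifelse(is.na(vals), 0, vals)
  out
}

# Normalize an interaction-type term for matching: extract the parenthesized
# human-readable term from forms like 'psi-mi:"MI:0915"(physical association)',
# strip quotes and a bare MI accession prefix, lowercase, trim.
normalize_type <- function(x) {
  out <- x
  m <- regexpr("\\(([^)]*)\\)", x)
  hit <- which(m > 0)
  out[hit] <- substr(x[hit], m[hit] + 1L, m[hit] + attr(m, "match.length")[hit] - 2L)
  out <- gsub('"', "", out, fixed = TRUE)
  out <- sub("^psi-mi:", "", out, ignore.case = TRUE)
  out <- sub("^MI:[0-9]+\\s*", "", out, ignore.case = TRUE)
  tolower(trimws(out))
}

#' Filter interaction evidence to a positive pair set
#'
#' Applies the positive-set filters used for stringent benchmark
#' construction: evidence is retained only when its interaction type is one
#' of the allowed terms and its confidence score passes the threshold
#' (`miscore >= miscore_min`; a score exactly at the threshold is retained).
#' Retained pairs are canonicalized as unordered pairs, duplicates are
#' collapsed, and all pairs are labeled `1`.
#'
#' Type matching is case-insensitive on the human-readable term, after
#' stripping an optional PSI-MI accession prefix. Self-pairs (homodimers)
#' passing the filters are retained.
#'
#' @param evidence A tibble as returned by [read_evidence()].
#' @param miscore_min Minimum confidence score retained (default 0.45).
#' @param allowed_types Character vector of allowed interaction-type terms
#'   (default `c("direct interaction", "physical association")`).
#' @return A tibble with columns `id_a`, `id_b` (canonical order:
#'   `id_a <= id_b`) and `label` (all `1L`), one row per unique unordered
#'   pair.
#' @examples
#' ev <- tibble::tibble(
#'   id_a = c("P1", "P2", "P1"),
#'   id_b = c("P2", "P1", "P3"),
#'   interaction_type = c("physical association", "direct interaction",
#'                        "colocalization"),
#'   miscore = c(0.56, 0.9, 0.9)
#' )
#' filter_positives(ev)
#' @export
filter_positives <- function(evidence,
                             miscore_min = 0.45,
                             allowed_types = c(
                               "direct interaction",
                               "physical association"
                             )) {
  if (!is.numeric(miscore_min) || miscore_min < 0 || miscore_min > 1) {
    abort("`miscore_min` must be a number in [0, 1].")
  }
  if (length(allowed_types) == 0) {
    abort("`allowed_types` must be nonempty.")
  }
  assert_pair_table(evidence, "evidence")
  # Idempotence: an already-filtered positive pair table passes through
  # unchanged (no evidence columns left to filter on).
  if (!all(c("interaction_type", "miscore") %in% names(evidence))) {
    if (!("label" %in% names(evidence)) || !all(evidence$label == 1L)) {
      abort("`evidence` must carry interaction_type and miscore columns, or be an all-positive pair table.")
    }
    out <- canonicalize_pair_cols(evidence[, c("id_a", "id_b")])
    out$label <- 1L
    return(distinct(as_tibble(out)))
  }
  wanted <- tolower(trimws(allowed_types))
  keep <- normalize_type(evidence$interaction_type) %in% wanted &
    evidence$miscore >= miscore_min
  out <- canonicalize_pair_cols(evidence[keep, c("id_a", "id_b"), drop = FALSE])
  out$label <- 1L
  distinct(as_tibble(out))
}

#' Read or write a labeled pair set as TSV
#'
#' Pair sets are exchanged as headerless three-column TSV:
#' `id_a<TAB>id_b<TAB>label`.
#'
#' @param pairs A pair tibble with columns `id_a`, `id_b`, `label`.
#' @param path File path.
#' @return `read_pairs()` returns a canonicalized pair tibble;
#'   `write_pairs()` invisibly returns `pairs`.
#' @export
write_pairs <- function(pairs, path) {
  assert_pair_table(pairs)
  readr::write_tsv(pairs[, c("id_a", "id_b", "label")], path, col_names = FALSE)
  invisible(pairs)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("id_a", "id_b", "label"),
    col_types = readr::cols(
      id_a = readr::col_character(),
      id_b = readr::col_character(),
      label = readr::col_integer()
    ),
    progress = FALSE
  )
  if (!all(df$label %in% c(0L, 1L))) {
    abort("Pair labels must be 0 or 1.")
  }
  out <- distinct(canonicalize_pair_cols(df))
  as_tibble(out)
}
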