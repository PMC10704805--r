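#' Generate a synthetic latent-factor interaction world
#'
#' Builds a fully seeded synthetic dataset on which every pipeline stage can
#' be exercised without any external download: proteins with random
#' sequences, per-protein embeddings, and a ground-truth interaction status
#' for every unordered protein pair.
#'
#' The generative model is bilinear in a latent space: each protein carries a
#' latent vector \eqn{z_i \sim N(0, I_k)}; the pair (i, j) interacts with
#' probability \eqn{\sigma(signal \cdot \langle z_i, z_j\rangle + bias)},
#' where the bias is calibrated numerically so the marginal positive
#' prevalence over all pairs is `1 / (ratio + 1)`. Observed embeddings are a
#' fixed random orthonormal linear map of the latents plus isotropic
#' Gaussian noise, so a model that is linear in the Hadamard product of two
#' embeddings can represent the ground-truth score (see the methods
#' vignette). Interaction statuses are drawn once per pair at world creation.
#'
#' Sequences are i.i.d. draws over the 20-letter alphabet and exist only to
#' exercise sequence encoders and identity filtering; they carry no
#' interaction signal.
#'
#' @param n_proteins Number of proteins (>= 4; default 500).
#' @param latent_dim Latent dimensionality (default 8).
#' @param embed_dim Observed embedding dimensionality (default 64; must be
#'   >= `latent_dim`).
#' @param signal Interaction-determinism strength (>= 0; default 4). At 0,
#'   interactions are independent of the embeddings.
#' @param noise_sd Embedding noise standard deviation (default 0.1).
#' @param n_positives Default number of positives drawn by
#'   [sample_labeled_pairs()] (default 1000).
#' @param ratio Negatives per positive; also sets the calibrated prevalence
#'   `1/(ratio+1)` (default 10).
#' @param seq_length_range Sequence length range (default 50-200).
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration and this seed.
#' @return A `synthetic_world` object: list with `proteins` (tibble `id`,
#'   `sequence`), `embeddings` (an [embedding_table()]), `truth` (tibble
#'   `id_a`, `id_b`, `prob`, `label` over all unordered pairs), and the
#'   configuration.
#' @export
synthetic_world <- function(n_proteins = 500,
                            latent_dim = 8,
                            embed_dim = 64,
                            signal = 4,
                            noise_sd = 0.1,
                            n_positives = 1000,
                            ratio = 10,
                            seq_length_range = c(50L, 200L),
                            seed = 1L) {
  if (n_proteins < 4) abort("`n_proteins` must be >= 4.")
  if (latent_dim > embed_dim) abort("`latent_dim` must be <= `embed_dim`.")
  if (signal < 0 || noise_sd < 0) abort("`signal` and `noise_sd` must be >= 0.")
  if (n_positives < 1) abort("`n_positives` must be >= 1.")
  if (n_proteins > 3000) {
    abort("`n_proteins` above 3000 would enumerate too many pairs; use a smaller world.")
  }
  target_prev <- 1 / (ratio + 1)

  withr::with_seed(seed, {
    ids <- sprintf("sp%04d", seq_len(n_proteins))
    z <- matrix(rnorm(n_proteins * latent_dim), n_proteins, latent_dim)
    # orthonormal embedding map: latents are exactly recoverable up to noise
    map <- qr.Q(qr(matrix(rnorm(embed_dim * latent_dim), embed_dim, latent_dim)))
    emb <- z %*% t(map) + noise_sd * matrix(rnorm(n_proteins * embed_dim),
      n_proteins, embed_dim
    )
    rownames(emb) <- ids

    i <- rep.int(seq_len(n_proteins - 1), times = (n_proteins - 1):1)
    j <- sequence((n_proteins - 1):1, from = 2:n_proteins)
    dots <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
    bias <- calibrate_bias(signal * dots, target_prev)
    prob <- plogis(signal * dots + bias)
    label <- as.integer(runif(length(prob)) < prob)

    lens <- sample(seq(seq_length_range[1], seq_length_range[2]), n_proteins,
      replace = TRUE
    )
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
    }, character(1))
  })

  structure(
    list(
      proteins = tibble(id = ids, sequence = seqs),
      embeddings = embedding_table(emb),
      truth = tibble(id_a = ids[i], id_b = ids[j], prob = prob, label = label),
      latent = z,
      config = list(
        n_proteins = n_proteins, latent_dim = latent_dim,
        embed_dim = embed_dim, signal = signal, noise_sd = noise_sd,
        n_positives = n_positives, ratio = ratio, seed = seed,
        bias = bias, target_prevalence = target_prev
      )
    ),
    class = "synthetic_world"
  )
}

# Solve mean(plogis(eta + b)) == target for b. The mean is strictly
# increasing in b, so the root is unique; it always exists for finite eta.
calibrate_bias <- function(eta, target) {
  f <- function(b) mean(plogis(eta + b)) - target
  sol <- tryCatch(
    uniroot(f, lower = -60, upper = 60, tol = 1e-10),
    error = function(e) NULL
  )
  if (is.null(sol)) {
    abort(sprintf("Prevalence calibration to %.4g is infeasible.", target))
  }
  sol$root
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic interaction world: %d proteins, latent dim %d, embed dim %d\n",
    cfg$n_proteins, cfg$latent_dim, cfg$embed_dim
  ))
  cat(sprintf(
    "  signal %.3g, noise sd %.3g, seed %d; positive prevalence %.4f (target %.4f)\n",
    cfg$signal, cfg$noise_sd, cfg$seed, mean(x$truth$label), cfg$target_prevalence
  ))
  invisible(x)
}

#' Draw a labeled pair set from a synthetic world
#'
#' Samples exactly `n_positives` ground-truth interacting pairs (label 1) and
#' `ratio * n_positives` non-interacting pairs (label 0) uniformly without
#' replacement from the world's pair universe, reproducibly under `seed`.
#'
#' @param world A [synthetic_world()].
#' @param n_positives,ratio Defaults taken from the world configuration.
#' @param seed Integer seed for the draw.
#' @return A pair tibble `id_a`, `id_b`, `label`.
#' @export
sample_labeled_pairs <- function(world,
                                 n_positives = NULL,
                                 ratio = NULL,
                                 seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  n_positives <- n_positives %||% world$config$n_positives
  ratio <- ratio %||% world$config$ratio
  pos_idx <- which(world$truth$label == 1L)
  neg_idx <- which(world$truth$label == 0L)
  n_neg <- ratio * n_positives
  if (length(pos_idx) < n_positives || length(neg_idx) < n_neg) {
    abort(sprintf(
      "World too small: %d/%d positives and %d/%d negatives available.",
      length(pos_idx), n_positives, length(neg_idx), n_neg
    ))
  }
  withr::with_seed(seed, {
    take_pos <- sample(pos_idx, n_positives)
    take_neg <- sample(neg_idx, n_neg)
  })
  out <- world$truth[c(sort(take_pos), sort(take_neg)), c("id_a", "id_b", "label")]
  as_tibble(out)
}

#' Export a synthetic world to pipeline input files
#'
#' Writes `proteins.fasta`, `embeddings.tsv` and `pairs.tsv` (a labeled pair
#' set drawn with [sample_labeled_pairs()]) into `dir`, ready for the
#' file-based pipeline entry points.
#'
#' @param world A [synthetic_world()].
#' @param dir Output directory (created if needed).
#' @param seed Seed for the pair draw.
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(
    paste0(">", world$proteins$id, "\n", world$proteins$sequence),
    file.path(dir, "proteins.fasta")
  )
  write_embeddings(world$embeddings, file.path(dir, "embeddings.tsv"))
  write_pairs(
    sample_labeled_pairs(world, seed = seed),
    file.path(dir, "pairs.tsv")
  )
  invisible(dir)
}
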