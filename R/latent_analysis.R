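## latent_analysis: procedures that probe what a learned latent space has
## captured — kNN activity classification, cosine-distance percentile
## binning against Tanimoto fingerprint similarity, and nearest-neighbour
## descriptor correlation.

## cosine distance matrix between rows of A (queries) and rows of B
.cosine_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  1 - (A / na) %*% t(B / nb)
}

#' k-nearest-neighbour classification in a latent space
#'
#' Majority vote among the k nearest training vectors by cosine distance;
#' the score is the positive-vote fraction. Distance ties and split votes
#' break deterministically (lowest training index / nearest neighbour's
#' label).
#'
#' @param train_x matrix of training vectors (rows).
#' @param train_y binary labels (0/1) aligned with `train_x`.
#' @param test_x matrix of query vectors.
#' @param k number of neighbours, `1 <= k <= nrow(train_x)`.
#' @param test_y optional query labels; when given, accuracy/AUPRC/AUROC
#'   are reported.
#' @return list with `pred`, `score`, and `metrics` (a
#'   [compute_metrics()] report or `NULL`).
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 5, test_y = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  n <- nrow(train_x)
  if (n == 0) .stopf("empty training set")
  if (k < 1 || k > n) .stopf("k must be in [1, %d]", n)
  stopifnot(length(train_y) == n, all(train_y %in% c(0, 1)))
  D <- .cosine_dist(test_x, train_x)
  score <- numeric(nrow(test_x)); pred <- numeric(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nb <- order(D[i, ])[seq_len(k)]     # stable: ties to lowest index
    votes <- train_y[nb]
    score[i] <- mean(votes)
    pred[i] <- if (score[i] > 0.5) 1
      else if (score[i] < 0.5) 0
      else votes[1]                     # split vote: nearest neighbour
  }
  metrics <- if (!is.null(test_y))
    compute_metrics(test_y, score, "classification") else NULL
  list(pred = pred, score = score, metrics = metrics)
}

#' Tanimoto similarity profile over latent-distance percentile bins
#'
#' Ranks all reference molecules by cosine distance of their latent to the
#' query's, splits the ranking into `n_bins` equal percentile bins (bin 1
#' nearest), samples up to `per_bin` molecules per bin, and reports the
#' mean and dispersion of their fingerprint Tanimoto similarity to the
#' query. A learned space that respects chemical similarity shows mean
#' Tanimoto decreasing with bin index.
#'
#' @param query a `molecule`.
#' @param references corpus or list of `molecule`.
#' @param model an `mtss_model` (or `gin_encoder`) used as embedder.
#' @param fingerprints optional precomputed reference fingerprint matrix;
#'   computed from the references when missing.
#' @param n_bins number of percentile bins.
#' @param per_bin sampling cap per bin.
#' @param seed sampling seed.
#' @return data.frame of class `similarity_profile`: `bin`, `n`,
#'   `mean_tanimoto`, `sd_tanimoto`, `mean_cosine_dist`.
#' @export
similarity_profile <- function(query, references, model,
                               fingerprints = NULL, n_bins = 10,
                               per_bin = 1000, seed = 1) {
  mols <- if (!is.null(references$molecules)) references$molecules
          else references
  N <- length(mols)
  if (N < n_bins) .stopf("need at least %d reference molecules", n_bins)
  enc <- if (inherits(model, "mtss_model")) model$encoder else model
  zq <- encode(enc, query)$latent
  zr <- encode(enc, mols)$latent
  d <- as.vector(.cosine_dist(zq, zr))
  if (max(d) - min(d) < 1e-12)
    .warnf("all reference distances are equal; bins are arbitrary")
  ord <- order(d)                       # ties: reference order
  fq <- compute_maccs(query)
  if (is.null(fingerprints)) fingerprints <- compute_maccs(mols)
  out <- data.frame(bin = seq_len(n_bins), n = 0L, mean_tanimoto = NA_real_,
                    sd_tanimoto = NA_real_, mean_cosine_dist = NA_real_)
  with_local_seed(seed, for (b in seq_len(n_bins)) {
    lo <- ceiling((b - 1) * N / n_bins) + 1L
    hi <- ceiling(b * N / n_bins)
    ranks <- ord[lo:hi]
    take <- if (length(ranks) > per_bin) sample(ranks, per_bin) else ranks
    tan <- vapply(take, function(j) tanimoto(fq, fingerprints[j, ]), 0)
    out$n[b] <- length(take)
    out$mean_tanimoto[b] <- mean(tan)
    out$sd_tanimoto[b] <- if (length(tan) > 1) stats::sd(tan) else 0
    out$mean_cosine_dist[b] <- mean(d[take])
  })
  class(out) <- c("similarity_profile", "data.frame")
  out
}

#' Nearest-neighbour descriptor correlation
#'
#' For each molecule, finds its nearest neighbour in latent space by
#' cosine distance (excluding itself, ties to the lowest index) and
#' computes the Spearman rank correlation between each descriptor of the
#' molecules and of their nearest neighbours. High correlations mean the
#' latent space organizes molecules by that property.
#'
#' @param latents matrix of latent vectors (rows).
#' @param descriptors data.frame of per-molecule descriptor values
#'   (e.g. from [compute_descriptors()]).
#' @return named numeric vector of Spearman r per descriptor; constant
#'   descriptors yield `NA`. Attribute `low_n` flags n < 3 neighbours
#'   situations (n = 2 gives trivially defined correlations).
#' @export
neighbor_descriptor_correlation <- function(latents, descriptors) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (n < 2) .stopf("need at least 2 molecules")
  stopifnot(nrow(descriptors) == n)
  D <- .cosine_dist(latents, latents)
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  res <- vapply(names(descriptors), function(nm) {
    x <- descriptors[[nm]]
    if (!is.numeric(x) || anyNA(x)) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(x[nn]) == 0) return(NA_real_)
    stats::cor(x, x[nn], method = "spearman")
  }, 0)
  structure(res, low_n = n < 3)
}
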