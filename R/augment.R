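## augment: the two self-supervision operators.
##  1. multi-granularity k-means over MACCS fingerprints -> pseudo-labels
##  2. connected-region graph mask -> contrastive view

# ---------------------------------------------------------------------------
# pseudo-labels

## k-means++ seeding (Arthur & Vassilvitskii) on rows of x
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Fit the multi-granularity pseudo-labeler
#'
#' One k-means model per granularity, fitted on binary fingerprints
#' treated as real vectors under Euclidean distance. Each model uses
#' k-means++ initialization with restarts and a 300-iteration cap;
#' clustering at several values of K yields coarse-to-fine structural
#' pseudo-labels for self-supervised classification.
#'
#' @param fingerprints matrix (n x 166) of 0/1 fingerprints, or a list of
#'   vectors.
#' @param granularities integer vector of K values, each >= 2, each <= n.
#' @param seed integer seed; fitting is deterministic given it.
#' @param n_restarts k-means++ restarts per granularity (best
#'   within-cluster sum of squares wins).
#' @return an object of class `pseudo_labeler` carrying per-granularity
#'   centroid matrices.
#' @export
fit_pseudo_labeler <- function(fingerprints, granularities, seed = 1,
                               n_restarts = 10) {
  x <- if (is.list(fingerprints)) do.call(rbind, fingerprints)
       else as.matrix(fingerprints)
  storage.mode(x) <- "double"
  n <- nrow(x)
  granularities <- as.integer(granularities)
  for (k in granularities) {
    if (k < 2) .stopf("granularity K=%d is below 2", k)
    if (k > n) .stopf("granularity K=%d exceeds corpus size N=%d", k, n)
  }
  centroids <- with_local_seed(seed, lapply(granularities, function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- .kmeanspp_centers(x, k)
      fit <- suppressWarnings(stats::kmeans(x, centers = init,
                                            iter.max = 300))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    unname(best$centers)
  }))
  structure(list(granularities = granularities, centroids = centroids,
                 seed = as.integer(seed), n = n),
            class = "pseudo_labeler")
}

#' @export
print.pseudo_labeler <- function(x, ...) {
  cat(sprintf("<pseudo_labeler> granularities (%s), fitted on %d fingerprints\n",
              paste(x$granularities, collapse = ", "), x$n))
  invisible(x)
}

#' Assign pseudo-labels by nearest centroid
#'
#' Labels are 0-based cluster indices, one per granularity (`0 <= label <
#' K`). Ties in centroid distance break to the lowest index.
#'
#' @param model a fitted [fit_pseudo_labeler()] model.
#' @param fingerprints one fingerprint vector or a matrix of rows.
#' @return for a single fingerprint an integer vector of length
#'   `length(granularities)`; for a matrix, an n x G integer matrix.
#' @export
assign_pseudo_labels <- function(model, fingerprints) {
  stopifnot(inherits(model, "pseudo_labeler"))
  single <- is.null(dim(fingerprints))
  x <- if (single) matrix(as.double(fingerprints), nrow = 1)
       else { x <- as.matrix(fingerprints); storage.mode(x) <- "double"; x }
  if (ncol(x) != ncol(model$centroids[[1]]))
    .stopf("fingerprint dimension %d does not match model dimension %d",
           ncol(x), ncol(model$centroids[[1]]))
  lab <- vapply(model$centroids, function(C) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(C))) - 2 * x %*% t(C) +
      outer(rep(1, nrow(x)), rowSums(C^2))
    max.col(-d2, ties.method = "first") - 1L   # 0-based, lowest index wins
  }, integer(nrow(x)))
  lab <- matrix(as.integer(lab), nrow = nrow(x))
  colnames(lab) <- paste0("K", model$granularities)
  if (single) lab[1, ] else lab
}

# ---------------------------------------------------------------------------
# graph mask

#' Mask a connected region of a molecular graph
#'
#' Starting from one seeded random atom, masking extends breadth-first to
#' neighbours (visited in ascending node index) until exactly
#' `ceiling(ratio * n_atoms)` atoms are masked; if a connected component is
#' exhausted first, a fresh unmasked start atom is drawn. Bonds whose two
#' endpoints are both masked are recorded as removed.
#'
#' @param graph a `mol_graph`.
#' @param ratio fraction of atoms to mask, in `[0, 1]`.
#' @param seed integer seed; the mask is deterministic given it.
#' @return an object of class `masked_graph` with fields `base`,
#'   `masked_nodes`, `removed_edges` (row indices into `base$edges`),
#'   `ratio`, `seed`.
#' @export
mask_graph <- function(graph, ratio, seed = 1) {
  stopifnot(inherits(graph, "mol_graph"), ratio >= 0, ratio <= 1)
  n <- graph$n_atoms
  quota <- .quota(ratio, n)
  masked <- logical(n)
  if (quota > 0) with_local_seed(seed, {
    n_masked <- 0L
    while (n_masked < quota) {
      start <- sample(which(!masked), 1)
      queue <- start
      queued <- logical(n); queued[start] <- TRUE
      while (length(queue) && n_masked < quota) {
        v <- queue[1]; queue <- queue[-1]
        if (!masked[v]) { masked[v] <- TRUE; n_masked <- n_masked + 1L }
        nb <- graph$adjacency[[v]]
        nb <- nb[!queued[nb] & !masked[nb]]
        if (length(nb)) { queued[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
  })
  masked_nodes <- which(masked)
  removed <- if (nrow(graph$edges))
    which(masked[graph$edges[, 1]] & masked[graph$edges[, 2]])
  else integer(0)
  structure(list(base = graph, masked_nodes = masked_nodes,
                 removed_edges = removed, ratio = ratio,
                 seed = as.integer(seed)),
            class = "masked_graph")
}

#' @export
print.masked_graph <- function(x, ...) {
  cat(sprintf("<masked_graph> %d/%d atoms masked, %d bonds removed (ratio %.2f)\n",
              length(x$masked_nodes), x$base$n_atoms,
              length(x$removed_edges), x$ratio))
  invisible(x)
}

#' Realize a masked graph as encoder input
#'
#' Masked atoms keep their place in the graph but their features are
#' replaced by a reserved mask token (atomic-number code 0, outside the
#' chemical vocabulary); bonds between two masked atoms are deleted while
#' bonds between a masked and an unmasked atom are retained. The encoder
#' thus sees graphs of equal order, and the contrastive pair
#' (original, masked) is well-defined.
#'
#' @param mg a [mask_graph()] result.
#' @return a `mol_graph`.
#' @export
apply_mask_for_encoding <- function(mg) {
  stopifnot(inherits(mg, "masked_graph"))
  g <- mg$base
  z <- g$atomic_number
  chir <- g$chirality
  z[mg$masked_nodes] <- 0L
  chir[mg$masked_nodes] <- CHIRALITY_CODES[["unspecified"]]
  keep <- setdiff(seq_len(nrow(g$edges)), mg$removed_edges)
  new_mol_graph(z, chir, g$aromatic,
                g$edges[keep, , drop = FALSE],
                g$bond_type[keep], g$bond_dir[keep])
}
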