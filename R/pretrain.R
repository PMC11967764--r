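## pretrain: the two self-supervised objectives and the joint optimizer.
##   L_MLCT  sum over granularities of mean cross-entropy between
##           structural-classifier logits and k-means pseudo-labels
##   L_MCL   mean Euclidean distance between the latents of each molecule
##           and its masked variant
##   L_all = L_MLCT + L_MCL (unweighted), minimized with Adam.

# ---------------------------------------------------------------------------
# structural classifier

#' Initialize the structural classifier
#'
#' Parallel fully connected heads, one per clustering granularity, mapping
#' the latent vector to K_i logits. With the reference granularities the
#' three heads have 100, 1000 and 10000 neurons.
#'
#' @param latent_dim input dimension.
#' @param granularities integer vector of K values.
#' @param seed initialization seed.
#' @return object of class `structural_classifier`.
#' @export
init_structural_classifier <- function(latent_dim, granularities, seed = 1) {
  heads <- with_local_seed(seed, lapply(granularities, function(k)
    list(W = .glorot(latent_dim, k), b = numeric(k))))
  structure(list(granularities = as.integer(granularities), heads = heads,
                 latent_dim = as.integer(latent_dim)),
            class = "structural_classifier")
}

#' @export
print.structural_classifier <- function(x, ...) {
  cat(sprintf("<structural_classifier> heads: %s (latent %d)\n",
              paste(x$granularities, collapse = ", "), x$latent_dim))
  invisible(x)
}

## stable log-softmax rows
.log_softmax <- function(L) {
  m <- apply(L, 1, max)
  L <- L - m
  L - log(rowSums(exp(L)))
}

#' Multi-granularity pseudo-label classification loss
#'
#' For each granularity i, `l_i` is the mean over the batch of the
#' cross-entropy between head-i logits and the 0-based pseudo-label;
#' the loss is the sum over granularities. Uniform logits therefore give
#' exactly `sum(log(K_i))`.
#'
#' @param classifier a [init_structural_classifier()].
#' @param latents batch matrix (n x latent_dim).
#' @param labels integer matrix (n x G) of 0-based pseudo-labels.
#' @param grad also return gradients (w.r.t. latents and head weights).
#' @return list with `loss`, `per_head` (vector of l_i), and when
#'   `grad = TRUE` the fields `g_latent` and `g_heads`.
#' @export
mlct_loss <- function(classifier, latents, labels, grad = FALSE) {
  stopifnot(inherits(classifier, "structural_classifier"))
  latents <- as.matrix(latents)
  labels <- matrix(as.integer(labels), nrow = nrow(latents))
  n <- nrow(latents)
  if (n == 0) .stopf("empty batch")
  G <- length(classifier$granularities)
  if (ncol(labels) != G)
    .stopf("label arity %d does not match %d heads", ncol(labels), G)
  per_head <- numeric(G)
  g_latent <- if (grad) matrix(0, n, ncol(latents))
  g_heads <- if (grad) vector("list", G)
  for (i in seq_len(G)) {
    K <- classifier$granularities[i]
    y <- labels[, i]
    if (any(y < 0L | y >= K))
      .stopf("pseudo-label out of range for head %d (K=%d)", i, K)
    h <- classifier$heads[[i]]
    logits <- sweep(latents %*% h$W, 2, h$b, "+")
    ls <- .log_softmax(logits)
    per_head[i] <- -mean(ls[cbind(seq_len(n), y + 1L)])
    if (grad) {
      Pr <- exp(ls)
      Pr[cbind(seq_len(n), y + 1L)] <- Pr[cbind(seq_len(n), y + 1L)] - 1
      Pr <- Pr / n
      g_heads[[i]] <- list(W = crossprod(latents, Pr), b = colSums(Pr))
      g_latent <- g_latent + Pr %*% t(h$W)
    }
  }
  out <- list(loss = sum(per_head), per_head = per_head)
  if (grad) { out$g_latent <- g_latent; out$g_heads <- g_heads }
  out
}

#' Masked-graph contrastive loss
#'
#' Mean over the batch of the Euclidean (L2) distance between each
#' original-graph latent and its masked-graph latent. A squared-distance
#' variant is available behind a flag.
#'
#' @param latents_original,latents_masked matrices of equal shape.
#' @param squared use squared Euclidean distance.
#' @param grad also return gradients.
#' @return list with `loss`, `distances`, and when `grad = TRUE` the
#'   fields `g_original` and `g_masked`.
#' @export
mcl_loss <- function(latents_original, latents_masked, squared = FALSE,
                     grad = FALSE) {
  A <- as.matrix(latents_original); B <- as.matrix(latents_masked)
  if (!all(dim(A) == dim(B))) .stopf("latent batch shape mismatch")
  n <- nrow(A)
  if (n == 0) .stopf("empty batch")
  D <- A - B
  d <- sqrt(rowSums(D^2))
  loss <- if (squared) mean(d^2) else mean(d)
  out <- list(loss = loss, distances = d)
  if (grad) {
    gA <- if (squared) 2 * D / n
          else D / (pmax(d, 1e-12) * n)
    out$g_original <- gA
    out$g_masked <- -gA
  }
  out
}

#' Combine the two pretraining losses
#'
#' `full` mode sums them with equal weight; the ablation modes keep a
#' single term.
#'
#' @param l_mlct,l_mcl loss values.
#' @param mode `"full"`, `"mlct_only"` or `"mcl_only"`.
#' @return the total loss.
#' @export
total_loss <- function(l_mlct, l_mcl, mode = "full") {
  mode <- match.arg(mode, c("full", "mlct_only", "mcl_only"))
  if (!is.finite(l_mlct) || !is.finite(l_mcl))
    .stopf("non-finite loss (l_mlct=%g, l_mcl=%g); aborting step",
           l_mlct, l_mcl)
  switch(mode, full = l_mlct + l_mcl, mlct_only = l_mlct, mcl_only = l_mcl)
}

#' Per-batch loss report
#'
#' @param l_mlct,l_mcl,per_head loss components.
#' @param mode training mode.
#' @return object of class `loss_report` with `l_all` equal to the mode's
#'   total.
#' @export
loss_report <- function(l_mlct, l_mcl, per_head = numeric(0),
                        mode = "full") {
  structure(list(l_mlct = l_mlct, l_mcl = l_mcl, per_head_ce = per_head,
                 l_all = total_loss(l_mlct, l_mcl, mode), mode = mode),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> l_all=%.4f (mlct=%.4f, mcl=%.4f, mode=%s)\n",
              x$l_all, x$l_mlct, x$l_mcl, x$mode))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Adam

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# pretraining loop

#' Pretraining configuration
#'
#' @param epochs,batch_size,learning_rate optimizer schedule (Adam with
#'   betas 0.9/0.999, no weight decay).
#' @param mask_ratio fraction of atoms masked per contrastive view.
#' @param granularities k-means K values for the pseudo-labeler; the
#'   reference setting is `c(100, 1000, 10000)`, desk-scale corpora use
#'   smaller values (the corpus must be at least as large as the biggest K).
#' @param mode `"full"` trains both objectives; `"mlct_only"` /
#'   `"mcl_only"` are the single-task ablations; `"none"` disables
#'   pretraining entirely (the no-pretraining ablation).
#' @param encoder an [encoder_config()].
#' @param mcl_squared use squared Euclidean distance in the contrastive
#'   loss.
#' @param seed root seed; clustering, initialization, shuffling and every
#'   per-epoch mask seed derive from it.
#' @return object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 30L, batch_size = 256L,
                            learning_rate = 1e-3, mask_ratio = 0.25,
                            granularities = c(100L, 1000L, 10000L),
                            mode = "full",
                            encoder = encoder_config(),
                            mcl_squared = FALSE, seed = 1) {
  mode <- match.arg(mode, c("full", "mlct_only", "mcl_only", "none"))
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            mask_ratio >= 0, mask_ratio <= 1, length(granularities) >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, mask_ratio = mask_ratio,
                 granularities = as.integer(granularities), mode = mode,
                 encoder = encoder, mcl_squared = isTRUE(mcl_squared),
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Multi-task self-supervised pretraining of the molecular encoder
#'
#' Fits the k-means pseudo-labeler once on the full corpus MACCS
#' fingerprints, then jointly minimizes the pseudo-label classification
#' loss and the masked-graph contrastive loss with Adam. One masked view
#' is drawn per molecule per epoch with a fresh derived seed, so runs are
#' replayable from the root seed.
#'
#' @param corpus a corpus from [generate_corpus()] / [read_corpus()], or a
#'   list of `molecule` objects.
#' @param config a [pretrain_config()].
#' @return object of class `mtss_model` with components `encoder`,
#'   `classifier`, `labeler`, `log` (per-epoch data.frame: losses,
#'   coarsest-head accuracy, mean contrastive distance) and `config`.
#'   `mode = "none"` returns the freshly initialized encoder with an
#'   empty log.
#' @export
#' @seealso [predict.mtss_model()], [finetune()]
mtss_pretrain <- function(corpus, config = pretrain_config()) {
  stopifnot(inherits(config, "pretrain_config"))
  mols <- if (!is.null(corpus$molecules)) corpus$molecules else corpus
  n <- length(mols)
  graphs <- lapply(mols, `[[`, "graph")
  enc <- init_encoder(config$encoder)
  cls <- init_structural_classifier(config$encoder$latent_dim,
                                    config$granularities,
                                    seed = derive_seed(config$seed, "heads"))
  empty_log <- data.frame(epoch = integer(0), l_mlct = numeric(0),
                          l_mcl = numeric(0), l_all = numeric(0),
                          acc_coarse = numeric(0), mcl_dist = numeric(0))
  if (config$mode == "none") {
    return(structure(list(encoder = enc, classifier = cls, labeler = NULL,
                          labels = NULL, log = empty_log, config = config,
                          n_masked_batches = 0L, call = match.call()),
                     class = "mtss_model"))
  }
  if (n < max(config$granularities))
    .stopf("corpus size %d is below the largest granularity K=%d", n,
           max(config$granularities))
  fps <- compute_maccs(mols)
  labeler <- fit_pseudo_labeler(fps, config$granularities,
                                seed = derive_seed(config$seed, "kmeans"))
  labels <- assign_pseudo_labels(labeler, fps)
  need_mask <- config$mode %in% c("full", "mcl_only")
  need_cls <- config$mode %in% c("full", "mlct_only")
  opt <- adam_init(c(enc$params, .flatten_heads(cls)))
  log <- empty_log
  n_masked_batches <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_local_seed(derive_seed(config$seed, paste0("shuffle", epoch)),
                           sample.int(n))
    starts <- seq(1, n, by = config$batch_size)
    ep <- c(l_mlct = 0, l_mcl = 0, acc = 0, dist = 0, nb = 0, nobs = 0)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      batch <- build_graph_batch(graphs[idx])
      fwd <- encoder_forward(enc, batch, keep_cache = TRUE)
      g_lat <- matrix(0, length(idx), config$encoder$latent_dim)
      l_mlct_v <- 0; l_mcl_v <- 0; per_head <- NULL; g_heads <- NULL
      if (need_cls) {
        ml <- mlct_loss(cls, fwd$latent, labels[idx, , drop = FALSE],
                        grad = TRUE)
        l_mlct_v <- ml$loss; per_head <- ml$per_head
        g_lat <- g_lat + ml$g_latent
        g_heads <- ml$g_heads
        acc <- mean(max.col(sweep(fwd$latent %*% cls$heads[[1]]$W, 2,
                                  cls$heads[[1]]$b, "+"),
                            ties.method = "first") - 1L ==
                    labels[idx, 1])
        ep["acc"] <- ep["acc"] + acc * length(idx)
      }
      grads_masked <- NULL
      if (need_mask) {
        n_masked_batches <- n_masked_batches + 1L
        mgraphs <- lapply(seq_along(idx), function(j)
          apply_mask_for_encoding(mask_graph(
            graphs[[idx[j]]], config$mask_ratio,
            seed = derive_seed(config$seed,
                               paste0("mask", epoch, "_", idx[j])))))
        mbatch <- build_graph_batch(mgraphs)
        mfwd <- encoder_forward(enc, mbatch, keep_cache = TRUE)
        cl <- mcl_loss(fwd$latent, mfwd$latent,
                       squared = config$mcl_squared, grad = TRUE)
        l_mcl_v <- cl$loss
        ep["dist"] <- ep["dist"] + sum(cl$distances)
        g_lat <- g_lat + cl$g_original
        grads_masked <- encoder_backward(enc, mbatch, mfwd, cl$g_masked)
      }
      l_all <- total_loss(l_mlct_v, l_mcl_v, config$mode)
      grads <- encoder_backward(enc, batch, fwd, g_lat)
      if (!is.null(grads_masked))
        for (nm in names(grads_masked))
          grads[[nm]] <- grads[[nm]] + grads_masked[[nm]]
      if (!is.null(g_heads))
        grads <- c(grads, .flatten_heads_grads(g_heads))
      upd <- adam_step(c(enc$params, .flatten_heads(cls)), grads, opt,
                       lr = config$learning_rate)
      opt <- upd$state
      enc$params <- upd$params[names(enc$params)]
      cls <- .unflatten_heads(cls, upd$params)
      ep["l_mlct"] <- ep["l_mlct"] + l_mlct_v * length(idx)
      ep["l_mcl"] <- ep["l_mcl"] + l_mcl_v * length(idx)
      ep["nobs"] <- ep["nobs"] + length(idx)
    }
    log <- rbind(log, data.frame(
      epoch = epoch,
      l_mlct = ep[["l_mlct"]] / ep[["nobs"]],
      l_mcl = ep[["l_mcl"]] / ep[["nobs"]],
      l_all = NA_real_,   # filled from the mode after the loop
      acc_coarse = if (need_cls) ep[["acc"]] / ep[["nobs"]] else NA_real_,
      mcl_dist = if (need_mask) ep[["dist"]] / ep[["nobs"]] else NA_real_))
  }
  log$l_all <- switch(config$mode,
                      full = log$l_mlct + log$l_mcl,
                      mlct_only = log$l_mlct,
                      mcl_only = log$l_mcl)
  structure(list(encoder = enc, classifier = cls, labeler = labeler,
                 labels = labels, log = log, config = config,
                 n_masked_batches = n_masked_batches, call = match.call()),
            class = "mtss_model")
}

.flatten_heads <- function(cls) {
  out <- list()
  for (i in seq_along(cls$heads)) {
    out[[paste0("head_W_", i)]] <- cls$heads[[i]]$W
    out[[paste0("head_b_", i)]] <- cls$heads[[i]]$b
  }
  out
}

.flatten_heads_grads <- function(g_heads) {
  out <- list()
  for (i in seq_along(g_heads)) {
    out[[paste0("head_W_", i)]] <- g_heads[[i]]$W
    out[[paste0("head_b_", i)]] <- g_heads[[i]]$b
  }
  out
}

.unflatten_heads <- function(cls, params) {
  for (i in seq_along(cls$heads)) {
    cls$heads[[i]]$W <- params[[paste0("head_W_", i)]]
    cls$heads[[i]]$b <- params[[paste0("head_b_", i)]]
  }
  cls
}

# ---------------------------------------------------------------------------
# model methods

#' @export
print.mtss_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Multi-task self-supervised molecular encoder (mode: %s)\n",
              cfg$mode))
  cat(sprintf("  encoder: %d GIN layers, graph %d-D, latent %d-D\n",
              cfg$encoder$n_layers, cfg$encoder$graph_dim,
              cfg$encoder$latent_dim))
  cat(sprintf("  pseudo-label granularities: %s\n",
              paste(cfg$granularities, collapse = ", ")))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs; final l_all=%.4f (mlct=%.4f, mcl=%.4f)\n",
                nrow(x$log), last$l_all, last$l_mlct, last$l_mcl))
  } else cat("  not pretrained\n")
  invisible(x)
}

#' @export
summary.mtss_model <- function(object, ...) {
  print(object)
  if (nrow(object$log)) {
    cat("\nTraining trajectory (first/last epochs):\n")
    ix <- unique(c(1, nrow(object$log)))
    print(object$log[ix, ], row.names = FALSE, digits = 4)
    if (!is.na(object$log$acc_coarse[nrow(object$log)]))
      cat(sprintf("\nCoarsest-head pseudo-label accuracy: %.3f (chance %.3f)\n",
                  object$log$acc_coarse[nrow(object$log)],
                  1 / object$config$granularities[1]))
  }
  invisible(object)
}

#' Embed molecules with a pretrained model
#'
#' @param object an `mtss_model`.
#' @param newdata molecules (corpus, list, `molecule`, or `mol_graph`).
#' @param type `"latent"` (projection-head output, the space used by the
#'   losses and analyses) or `"representation"` (pooled graph vector).
#' @param ... unused.
#' @return a numeric matrix, one row per molecule.
#' @export
predict.mtss_model <- function(object, newdata, type = c("latent",
                                                         "representation"),
                               ...) {
  type <- match.arg(type)
  encode(object$encoder, newdata)[[type]]
}

#' Plot the pretraining loss trajectory
#'
#' @param x an `mtss_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mtss_model <- function(x, ...) {
  if (!nrow(x$log)) {
    warning("model has no training log")
    return(invisible(x))
  }
  graphics::matplot(x$log$epoch, cbind(x$log$l_all, x$log$l_mlct, x$log$l_mcl),
                    type = "l", lty = 1:3, col = c("black", "steelblue",
                                                   "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("l_all", "l_mlct", "l_mcl"), lty = 1:3,
                   col = c("black", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}
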