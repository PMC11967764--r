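## finetune: supervised transfer of a pretrained encoder to property
## prediction — scaffold-based splitting, end-to-end fine-tuning with a
## 2-layer task head on the graph representation, and evaluation metrics.

# ---------------------------------------------------------------------------
# scaffold split

## Murcko-style scaffold key: prune terminal atoms iteratively until only
## ring systems and linkers remain; canonicalize the remaining subgraph
## (igraph BLISS with atom colors) into a string key. Acyclic molecules
## share the "ACYCLIC" scaffold, the usual convention.
murcko_scaffold_key <- function(graph) {
  n <- graph$n_atoms
  keep <- rep(TRUE, n)
  deg <- vapply(graph$adjacency, length, 0L)
  edges <- graph$edges
  repeat {
    d <- rep(0L, n)
    if (nrow(edges)) {
      live <- keep[edges[, 1]] & keep[edges[, 2]]
      tab <- table(factor(as.vector(edges[live, , drop = FALSE]),
                          levels = seq_len(n)))
      d <- as.integer(tab)
    }
    leaf <- keep & d <= 1L
    if (!any(leaf) || all(leaf == keep)) { keep[leaf] <- FALSE; break }
    keep[leaf] <- FALSE
  }
  verts <- which(keep)
  if (!length(verts)) return("ACYCLIC")
  live <- graph$edges[, 1] %in% verts & graph$edges[, 2] %in% verts
  e <- graph$edges[live, , drop = FALSE]
  bt <- graph$bond_type[live]
  colors <- graph$atomic_number[verts] * 2L + as.integer(graph$aromatic[verts])
  ig <- igraph::graph_from_edgelist(
    matrix(match(as.vector(e), verts), ncol = 2), directed = FALSE)
  if (igraph::vcount(ig) < length(verts))
    ig <- igraph::add_vertices(ig, length(verts) - igraph::vcount(ig))
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  ce <- cbind(perm[match(e[, 1], verts)], perm[match(e[, 2], verts)])
  ce <- t(apply(ce, 1, sort))
  ord <- order(ce[, 1], ce[, 2])
  paste(
    paste(colors[order(perm)], collapse = ","),
    paste(ce[ord, 1], ce[ord, 2], bt[ord], sep = "-", collapse = ","),
    sep = "|")
}

#' Scaffold-based train/validation/test split
#'
#' Molecules are grouped by the Murcko-style scaffold of their graph
#' (side chains pruned; all acyclic molecules share one group) and whole
#' groups are assigned greedily, largest first, to the split furthest
#' below its target fraction — so no scaffold ever straddles splits.
#'
#' @param molecules list of `molecule` (or a corpus).
#' @param fractions train/valid/test fractions summing to 1.
#' @param seed tie-break seed for equally sized groups.
#' @return list of integer index vectors `train`, `valid`, `test`. A
#'   warning is raised if any split ends up empty.
#' @export
scaffold_split <- function(molecules, fractions = c(0.8, 0.1, 0.1),
                           seed = 1) {
  if (!is.null(molecules$molecules)) molecules <- molecules$molecules
  n <- length(molecules)
  if (n < 3) .stopf("dataset smaller than 3 molecules")
  if (abs(sum(fractions) - 1) > 1e-8) .stopf("fractions must sum to 1")
  keys <- vapply(molecules, function(m) murcko_scaffold_key(m$graph), "")
  groups <- split(seq_len(n), keys)
  sizes <- lengths(groups)
  ord <- with_local_seed(seed, {
    jitter <- stats::runif(length(groups))
    order(-sizes, jitter)
  })
  targets <- fractions * n
  fill <- c(train = 0, valid = 0, test = 0)
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (gi in ord) {
    deficit <- targets - fill
    w <- which.max(deficit)
    out[[w]] <- c(out[[w]], groups[[gi]])
    fill[w] <- fill[w] + sizes[gi]
  }
  if (any(vapply(out, length, 0L) == 0))
    .warnf("scaffold split produced an empty subset (%d scaffold groups)",
           length(groups))
  lapply(out, sort)
}

#' Random train/validation/test split
#'
#' @inheritParams scaffold_split
#' @export
random_split <- function(molecules, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (!is.null(molecules$molecules)) molecules <- molecules$molecules
  n <- length(molecules)
  if (n < 3) .stopf("dataset smaller than 3 molecules")
  with_local_seed(seed, {
    ord <- sample.int(n)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    list(train = sort(ord[seq_len(n_tr)]),
         valid = sort(ord[n_tr + seq_len(n_va)]),
         test = sort(ord[(n_tr + n_va + 1):n]))
  })
}

#' Bundle molecules, labels and splits into a property dataset
#'
#' @param molecules list of `molecule` or a corpus.
#' @param labels numeric labels (binary 0/1 for classification).
#' @param task_type `"classification"` or `"regression"`; defaults to the
#'   `task_type` attribute of `labels` if present.
#' @param splits list with `train`/`valid`/`test` index vectors; every
#'   index must appear in exactly one split.
#' @return object of class `property_dataset`.
#' @export
property_dataset <- function(molecules, labels, task_type = NULL,
                             splits = NULL) {
  if (!is.null(molecules$molecules)) molecules <- molecules$molecules
  if (is.null(task_type))
    task_type <- attr(labels, "task_type") %||% "classification"
  task_type <- match.arg(task_type, c("classification", "regression"))
  n <- length(molecules)
  stopifnot(length(labels) == n)
  if (task_type == "classification" && !all(labels %in% c(0, 1)))
    .stopf("classification labels must be 0/1")
  if (is.null(splits)) splits <- random_split(molecules)
  ix <- sort(unlist(splits, use.names = FALSE))
  if (!identical(ix, seq_len(n)))
    .stopf("splits must partition 1..%d exactly", n)
  structure(list(molecules = molecules, labels = as.numeric(labels),
                 task_type = task_type, splits = splits),
            class = "property_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset> %d molecules, %s; splits %d/%d/%d\n",
              length(x$molecules), x$task_type,
              length(x$splits$train), length(x$splits$valid),
              length(x$splits$test)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# metrics

#' Evaluation metrics for property prediction
#'
#' Classification: AUROC from the Mann-Whitney rank statistic (midranks
#' for ties), AUPRC by average-precision integration of the
#' precision-recall curve, accuracy at a 0.5 score threshold.
#' Regression: RMSE, MAE, Pearson and Spearman correlations.
#'
#' @param y_true observed labels.
#' @param y_score predicted scores (probabilities or real predictions).
#' @param task_type `"classification"` or `"regression"`.
#' @return object of class `metrics_report` (a named list).
#' @export
compute_metrics <- function(y_true, y_score,
                            task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  stopifnot(length(y_true) == length(y_score), length(y_true) >= 2)
  if (task_type == "classification") {
    if (length(unique(y_true)) < 2)
      .stopf("single-class y_true: AUROC undefined")
    structure(list(auroc = .auroc(y_true, y_score),
                   auprc = .auprc(y_true, y_score),
                   accuracy = mean((y_score > 0.5) == (y_true == 1)),
                   task_type = task_type, n = length(y_true)),
              class = "metrics_report")
  } else {
    pr <- if (stats::sd(y_true) == 0 || stats::sd(y_score) == 0) NA_real_
          else stats::cor(y_true, y_score)
    sr <- if (stats::sd(y_true) == 0 || stats::sd(y_score) == 0) NA_real_
          else stats::cor(y_true, y_score, method = "spearman")
    structure(list(rmse = sqrt(mean((y_true - y_score)^2)),
                   mae = mean(abs(y_true - y_score)),
                   pearson_r = pr, spearman_r = sr,
                   task_type = task_type, n = length(y_true)),
              class = "metrics_report")
  }
}

## Mann-Whitney AUROC with midranks
.auroc <- function(y, s) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## average precision over distinct thresholds (ties grouped)
.auprc <- function(y, s) {
  ord <- order(-s)
  y <- y[ord]; s <- s[ord]
  npos <- sum(y == 1)
  if (npos == 0) return(NA_real_)
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y == 1)[grp_end]
  fp <- cumsum(y == 0)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.metrics_report <- function(x, ...) {
  if (x$task_type == "classification")
    cat(sprintf("<metrics> AUROC %.4f | AUPRC %.4f | accuracy %.4f (n=%d)\n",
                x$auroc, x$auprc, x$accuracy, x$n))
  else
    cat(sprintf("<metrics> RMSE %.4f | MAE %.4f | Pearson %.4f | Spearman %.4f (n=%d)\n",
                x$rmse, x$mae, x$pearson_r, x$spearman_r, x$n))
  invisible(x)
}

# ---------------------------------------------------------------------------
# fine-tuning

#' Fine-tuning configuration
#'
#' @param epochs,batch_size,learning_rate Adam schedule.
#' @param patience early-stopping patience on the validation metric
#'   (AUROC for classification, RMSE for regression).
#' @param head_hidden width of the task head's hidden layer.
#' @param freeze_encoder train only the head (linear-probe style); the
#'   default refines the entire model.
#' @param seed root seed.
#' @return object of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 60L, batch_size = 64L,
                            learning_rate = 1e-3, patience = 10L,
                            head_hidden = 64L, freeze_encoder = FALSE,
                            seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, patience >= 1, head_hidden >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 head_hidden = as.integer(head_hidden),
                 freeze_encoder = isTRUE(freeze_encoder),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Fine-tune a (pre)trained encoder on a property dataset
#'
#' Attaches a 2-layer task head to the graph representation and trains
#' end-to-end (encoder unfrozen by default) with binary cross-entropy or
#' mean squared error. Early-stops on the validation metric and reports
#' test metrics at the best validation epoch.
#'
#' @param encoder a `gin_encoder` or an `mtss_model` (its encoder is
#'   used).
#' @param dataset a [property_dataset()].
#' @param config a [finetune_config()].
#' @return object of class `mtss_finetune` with `metrics` (per split),
#'   `log`, the fine-tuned `encoder` and `head`.
#' @export
finetune <- function(encoder, dataset, config = finetune_config()) {
  if (inherits(encoder, "mtss_model")) encoder <- encoder$encoder
  stopifnot(inherits(encoder, "gin_encoder"),
            inherits(dataset, "property_dataset"),
            inherits(config, "finetune_config"))
  task <- dataset$task_type
  y <- dataset$labels
  sp <- dataset$splits
  for (nm in c("train", "valid", "test"))
    if (!length(sp[[nm]])) .stopf("empty %s split", nm)
  if (task == "classification" && length(unique(y[sp$train])) < 2)
    .stopf("single-class training labels")
  graphs <- lapply(dataset$molecules, `[[`, "graph")
  gdim <- encoder$config$graph_dim
  head <- with_local_seed(derive_seed(config$seed, "head"), list(
    W1 = .glorot(gdim, config$head_hidden), b1 = numeric(config$head_hidden),
    W2 = .glorot(config$head_hidden, 1L), b2 = 0))
  params <- c(encoder$params, list(ft_W1 = head$W1, ft_b1 = head$b1,
                                   ft_W2 = head$W2, ft_b2 = head$b2))
  opt <- adam_init(params)
  head_fwd <- function(rep_mat, params) {
    U <- sweep(rep_mat %*% params$ft_W1, 2, params$ft_b1, "+")
    R <- .relu(U)
    list(U = U, R = R,
         out = as.vector(R %*% params$ft_W2 + params$ft_b2))
  }
  predict_split <- function(params, idx) {
    enc2 <- encoder; enc2$params <- params[names(encoder$params)]
    out <- numeric(length(idx))
    for (s in seq(1, length(idx), by = 512)) {
      ii <- idx[s:min(s + 511, length(idx))]
      b <- build_graph_batch(graphs[ii])
      f <- encoder_forward(enc2, b)
      out[match(ii, idx)] <- head_fwd(f$representation, params)$out
    }
    if (task == "classification") stats::plogis(out) else out
  }
  val_metric <- function(params) {
    sc <- predict_split(params, sp$valid)
    if (task == "classification") {
      if (length(unique(y[sp$valid])) < 2) return(NA_real_)
      .auroc(y[sp$valid], sc)
    } else -sqrt(mean((y[sp$valid] - sc)^2))   # maximize
  }
  best <- list(metric = -Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    valid_metric = numeric(0))
  ntr <- length(sp$train)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_local_seed(derive_seed(config$seed, paste0("ft_shuf", epoch)),
                           sample(sp$train))
    ep_loss <- 0
    for (s in seq(1, ntr, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
      enc2 <- encoder; enc2$params <- params[names(encoder$params)]
      b <- build_graph_batch(graphs[idx])
      f <- encoder_forward(enc2, b, keep_cache = TRUE)
      hf <- head_fwd(f$representation, params)
      yy <- y[idx]; m <- length(idx)
      if (task == "classification") {
        p <- stats::plogis(hf$out)
        loss <- -mean(yy * log(pmax(p, 1e-12)) +
                        (1 - yy) * log(pmax(1 - p, 1e-12)))
        g_out <- (p - yy) / m
      } else {
        loss <- mean((hf$out - yy)^2)
        g_out <- 2 * (hf$out - yy) / m
      }
      if (!is.finite(loss)) .stopf("non-finite fine-tuning loss")
      ep_loss <- ep_loss + loss * m
      g_out <- matrix(g_out, ncol = 1)
      grads <- list(ft_W2 = crossprod(hf$R, g_out), ft_b2 = sum(g_out))
      gR <- g_out %*% t(params$ft_W2)
      gU <- gR * (hf$U > 0)
      grads$ft_W1 <- crossprod(f$representation, gU)
      grads$ft_b1 <- colSums(gU)
      if (!config$freeze_encoder) {
        g_rep <- gU %*% t(params$ft_W1)
        zero_lat <- matrix(0, m, encoder$config$latent_dim)
        eg <- encoder_backward(enc2, b, f, zero_lat, g_rep = g_rep)
        grads <- c(grads, eg)
      }
      upd <- adam_step(params, grads, opt, lr = config$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    vm <- val_metric(params)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / ntr,
                                 valid_metric = vm))
    if (!is.na(vm) && vm > best$metric) {
      best <- list(metric = vm, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  params <- best$params
  metrics <- lapply(sp, function(idx) {
    sc <- predict_split(params, idx)
    if (task == "classification" && length(unique(y[idx])) < 2) return(NULL)
    compute_metrics(y[idx], sc, task)
  })
  enc_out <- encoder; enc_out$params <- params[names(encoder$params)]
  structure(list(encoder = enc_out,
                 head = params[c("ft_W1", "ft_b1", "ft_W2", "ft_b2")],
                 task_type = task, metrics = metrics, log = log,
                 best_epoch = best$epoch, config = config),
            class = "mtss_finetune")
}

#' @export
print.mtss_finetune <- function(x, ...) {
  cat(sprintf("<mtss_finetune> %s, best epoch %d\n", x$task_type,
              x$best_epoch))
  if (!is.null(x$metrics$test)) { cat("  test: "); print(x$metrics$test) }
  invisible(x)
}

#' Predict property scores with a fine-tuned model
#'
#' @param object an `mtss_finetune`.
#' @param newdata molecules.
#' @param ... unused.
#' @return numeric vector: class-1 probabilities for classification,
#'   predictions for regression.
#' @export
predict.mtss_finetune <- function(object, newdata, ...) {
  gl <- .as_graph_list(newdata)
  b <- build_graph_batch(gl)
  f <- encoder_forward(object$encoder, b)
  U <- sweep(f$representation %*% object$head$ft_W1, 2, object$head$ft_b1,
             "+")
  out <- as.vector(.relu(U) %*% object$head$ft_W2 + object$head$ft_b2)
  if (object$task_type == "classification") stats::plogis(out) else out
}
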