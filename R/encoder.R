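## encoder: GIN molecular encoder.
##   atom/bond feature embeddings -> n_layers of AGGREGATE/COMBINE message
##   passing (sum over neighbours with additive bond-feature embeddings,
##   2-layer MLP update, epsilon = 0) -> mean-pool READOUT -> projection
##   head to the latent space.
## Forward and backward passes are written directly in base R matrix
## algebra; sparse scatter/pool matrices come from Matrix.

.N_ATOM_TYPES <- 119L   # atomic numbers 1..118 plus mask token (code 0)
.N_CHIRALITY <- 4L
.N_BOND_TYPES <- 4L
.N_BOND_DIRS <- 3L

#' Encoder configuration
#'
#' Defaults mirror the reference architecture: a 5-layer graph
#' convolution with ReLU activation, a 512-D graph representation from
#' mean pooling, and a one-hidden-layer projection MLP onto a 256-D
#' latent space. `hidden_dim` is the width of the intermediate
#' message-passing layers; the final layer realizes `graph_dim`.
#'
#' @param n_layers number of message-passing rounds (>= 1).
#' @param hidden_dim width of intermediate node states.
#' @param graph_dim dimension of the pooled graph representation.
#' @param latent_dim dimension of the projection-head output.
#' @param seed parameter-initialization seed.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 5L, hidden_dim = 300L,
                           graph_dim = 512L, latent_dim = 256L, seed = 1) {
  if (n_layers < 1) .stopf("n_layers must be >= 1")
  if (min(hidden_dim, graph_dim, latent_dim) < 1)
    .stopf("all dimensions must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 graph_dim = as.integer(graph_dim),
                 latent_dim = as.integer(latent_dim),
                 activation = "relu",
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config> %d layers, hidden %d, graph %d, latent %d\n",
              x$n_layers, x$hidden_dim, x$graph_dim, x$latent_dim))
  invisible(x)
}

.glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

## layer widths: d_0 = hidden (embedding dim), d_k = hidden for k < n,
## d_n = graph_dim
.layer_dims <- function(cfg) {
  dims <- rep(cfg$hidden_dim, cfg$n_layers + 1L)
  dims[cfg$n_layers + 1L] <- cfg$graph_dim
  dims
}

#' Initialize the GIN encoder
#'
#' Deterministic for a fixed seed. Embedding tables cover the full atom
#' and bond vocabularies plus the mask token used by contrastive
#' pretraining.
#'
#' @param config an [encoder_config()].
#' @return object of class `gin_encoder` holding `config` and `params`
#'   (a named list of weight matrices).
#' @export
init_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  dims <- .layer_dims(config)
  params <- with_local_seed(config$seed, {
    p <- list(
      atom_z = matrix(stats::rnorm(.N_ATOM_TYPES * dims[1], 0, 0.1),
                      .N_ATOM_TYPES, dims[1]),
      atom_chir = matrix(stats::rnorm(.N_CHIRALITY * dims[1], 0, 0.1),
                         .N_CHIRALITY, dims[1]))
    for (k in seq_len(config$n_layers)) {
      din <- dims[k]; dout <- dims[k + 1L]
      p[[paste0("bond_t_", k)]] <- matrix(
        stats::rnorm(.N_BOND_TYPES * din, 0, 0.1), .N_BOND_TYPES, din)
      p[[paste0("bond_d_", k)]] <- matrix(
        stats::rnorm(.N_BOND_DIRS * din, 0, 0.1), .N_BOND_DIRS, din)
      p[[paste0("W1_", k)]] <- .glorot(din, dout)
      p[[paste0("b1_", k)]] <- numeric(dout)
      p[[paste0("W2_", k)]] <- .glorot(dout, dout)
      p[[paste0("b2_", k)]] <- numeric(dout)
    }
    p$proj_W1 <- .glorot(config$graph_dim, config$graph_dim)
    p$proj_b1 <- numeric(config$graph_dim)
    p$proj_W2 <- .glorot(config$graph_dim, config$latent_dim)
    p$proj_b2 <- numeric(config$latent_dim)
    p
  })
  structure(list(config = config, params = params), class = "gin_encoder")
}

#' @export
print.gin_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<gin_encoder> %d layers, %d parameters\n",
              x$config$n_layers, np))
  invisible(x)
}

# ---------------------------------------------------------------------------
# batching

## Pack a list of mol_graph into one block-diagonal batch:
##   z, chir          per-node feature indices (z shifted so mask token = 1)
##   src, dst, bt, bd directed edge lists (each undirected bond twice)
##   S                sparse N x E scatter matrix: S %*% msg sums incoming
##                    messages per destination node
##   P                sparse G x N mean-pool matrix
build_graph_batch <- function(graphs) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  sizes <- vapply(graphs, `[[`, 0L, "n_atoms")
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  z <- unlist(lapply(graphs, `[[`, "atomic_number")) + 1L  # mask token -> 1
  chir <- unlist(lapply(graphs, `[[`, "chirality"))
  src <- dst <- bt <- bd <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$edges)) {
      u <- g$edges[, 1] + offs[i]; v <- g$edges[, 2] + offs[i]
      src[[i]] <- c(u, v); dst[[i]] <- c(v, u)
      bt[[i]] <- rep(g$bond_type, 2); bd[[i]] <- rep(g$bond_dir, 2)
    }
  }
  src <- unlist(src); dst <- unlist(dst)
  bt <- unlist(bt); bd <- unlist(bd)
  E <- length(src)
  S <- if (E) Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1,
                                   dims = c(N, E))
       else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(N, 0))
  P <- Matrix::sparseMatrix(i = rep(seq_along(graphs), sizes),
                            j = seq_len(N),
                            x = rep(1 / sizes, sizes),
                            dims = c(length(graphs), N))
  list(z = z, chir = chir, src = src, dst = dst, bt = bt, bd = bd,
       S = S, P = P, n_nodes = N, n_graphs = length(graphs), sizes = sizes)
}

.relu <- function(x) { x[x < 0] <- 0; x }

# ---------------------------------------------------------------------------
# forward

## Full forward pass over a packed batch. Returns representations (G x
## graph_dim), latents (G x latent_dim) and, if keep_cache, every
## intermediate needed by the backward pass.
encoder_forward <- function(encoder, batch, keep_cache = FALSE) {
  p <- encoder$params
  nl <- encoder$config$n_layers
  H <- p$atom_z[batch$z, , drop = FALSE] +
       p$atom_chir[batch$chir, , drop = FALSE]
  cache <- if (keep_cache) list(H0 = H, layers = vector("list", nl))
  for (k in seq_len(nl)) {
    st <- message_passing_step(p, batch, H, k)
    if (keep_cache) cache$layers[[k]] <- st
    H <- st$H_out
  }
  hG <- as.matrix(batch$P %*% H)
  U <- sweep(hG %*% p$proj_W1, 2, p$proj_b1, "+")
  R <- .relu(U)
  latent <- sweep(R %*% p$proj_W2, 2, p$proj_b2, "+")
  out <- list(representation = hG, latent = latent)
  if (keep_cache) {
    cache$H_last <- H; cache$hG <- hG; cache$proj_U <- U; cache$proj_R <- R
    out$cache <- cache
  }
  out
}

#' One GIN message-passing step
#'
#' AGGREGATE: each node sums the states of its neighbours, each composed
#' additively with the bond-feature embedding of the connecting edge.
#' COMBINE: `h_v = MLP_k((1 + eps) * h_v_prev + a_v)` with `eps = 0` and a
#' 2-layer ReLU MLP. Exposed for inspection and testing; training uses
#' the batched driver internally.
#'
#' @param params encoder parameter list (`encoder$params`).
#' @param batch a packed batch from the internal batcher.
#' @param H node-state matrix from layer k-1.
#' @param k layer index.
#' @return list with `agg` (aggregated messages), `H_out` (updated
#'   states), and the intermediates `X`, `U1`, `R1`.
#' @export
message_passing_step <- function(params, batch, H, k) {
  Ebt <- params[[paste0("bond_t_", k)]]
  Ebd <- params[[paste0("bond_d_", k)]]
  if (length(batch$src)) {
    msg <- H[batch$src, , drop = FALSE] +
      Ebt[batch$bt, , drop = FALSE] + Ebd[batch$bd, , drop = FALSE]
    agg <- as.matrix(batch$S %*% msg)
  } else {
    msg <- matrix(0, 0, ncol(H))
    agg <- matrix(0, nrow(H), ncol(H))
  }
  X <- H + agg                                   # (1 + eps) h + a, eps = 0
  U1 <- sweep(X %*% params[[paste0("W1_", k)]], 2,
              params[[paste0("b1_", k)]], "+")
  R1 <- .relu(U1)
  H_out <- sweep(R1 %*% params[[paste0("W2_", k)]], 2,
                 params[[paste0("b2_", k)]], "+")
  list(agg = agg, H_out = H_out, X = X, U1 = U1, R1 = R1, msg = msg)
}

# ---------------------------------------------------------------------------
# backward

## Backpropagate gradients w.r.t. latent (G x latent_dim) and optionally
## w.r.t. the pooled representation (G x graph_dim). Returns a grads list
## with the same names/shapes as encoder$params.
encoder_backward <- function(encoder, batch, fwd, g_latent, g_rep = NULL) {
  p <- encoder$params
  nl <- encoder$config$n_layers
  cache <- fwd$cache
  grads <- list()
  # projection head
  grads$proj_W2 <- crossprod(cache$proj_R, g_latent)
  grads$proj_b2 <- colSums(g_latent)
  gR <- g_latent %*% t(p$proj_W2)
  gU <- gR * (cache$proj_U > 0)
  grads$proj_W1 <- crossprod(cache$hG, gU)
  grads$proj_b1 <- colSums(gU)
  g_hG <- gU %*% t(p$proj_W1)
  if (!is.null(g_rep)) g_hG <- g_hG + g_rep
  # readout
  gH <- as.matrix(Matrix::crossprod(batch$P, g_hG))
  # message-passing layers, reverse order
  for (k in rev(seq_len(nl))) {
    st <- cache$layers[[k]]
    grads[[paste0("W2_", k)]] <- crossprod(st$R1, gH)
    grads[[paste0("b2_", k)]] <- colSums(gH)
    gR1 <- gH %*% t(p[[paste0("W2_", k)]])
    gU1 <- gR1 * (st$U1 > 0)
    grads[[paste0("W1_", k)]] <- crossprod(st$X, gU1)
    grads[[paste0("b1_", k)]] <- colSums(gU1)
    gX <- gU1 %*% t(p[[paste0("W1_", k)]])
    # gX flows to both h_v (identity) and the aggregation
    if (length(batch$src)) {
      gmsg <- as.matrix(Matrix::crossprod(batch$S, gX))   # per directed edge
      gH_new <- gX
      # scatter message gradients back to source nodes
      gsrc <- rowsum(gmsg, batch$src)
      idx <- as.integer(rownames(gsrc))
      gH_new[idx, ] <- gH_new[idx, , drop = FALSE] + gsrc
      grads[[paste0("bond_t_", k)]] <- .rowsum_into(gmsg, batch$bt,
                                                    .N_BOND_TYPES)
      grads[[paste0("bond_d_", k)]] <- .rowsum_into(gmsg, batch$bd,
                                                    .N_BOND_DIRS)
      gH <- gH_new
    } else {
      grads[[paste0("bond_t_", k)]] <- matrix(0, .N_BOND_TYPES,
                                              ncol(p[[paste0("bond_t_", k)]]))
      grads[[paste0("bond_d_", k)]] <- matrix(0, .N_BOND_DIRS,
                                              ncol(p[[paste0("bond_d_", k)]]))
      gH <- gX
    }
  }
  grads$atom_z <- .rowsum_into(gH, batch$z, .N_ATOM_TYPES)
  grads$atom_chir <- .rowsum_into(gH, batch$chir, .N_CHIRALITY)
  grads
}

## rowsum into a fixed number of rows (absent indices get zero rows)
.rowsum_into <- function(x, idx, nrows) {
  out <- matrix(0, nrows, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---------------------------------------------------------------------------
# public encode

#' Encode molecules into graph representations and latent vectors
#'
#' Runs the message-passing stack, mean-pools node states into the graph
#' representation `h_G`, and applies the projection head. The encoder has
#' no stochastic layers, so encoding is deterministic.
#'
#' @param encoder a `gin_encoder`.
#' @param graphs a `mol_graph`, a `molecule`, or a list of either.
#' @return list with `representation` (n x graph_dim matrix) and `latent`
#'   (n x latent_dim matrix).
#' @export
encode <- function(encoder, graphs) {
  stopifnot(inherits(encoder, "gin_encoder"))
  gl <- .as_graph_list(graphs)
  if (!length(gl)) .stopf("no graphs to encode")
  batch <- build_graph_batch(gl)
  out <- encoder_forward(encoder, batch)
  out[c("representation", "latent")]
}

.as_graph_list <- function(x) {
  if (inherits(x, "mol_graph")) return(list(x))
  if (inherits(x, "molecule")) return(list(x$graph))
  if (!is.null(x$molecules)) x <- x$molecules
  lapply(x, function(m) if (inherits(m, "molecule")) m$graph else m)
}
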