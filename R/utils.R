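#' @keywords internal
#' @import Matrix
#' @importFrom igraph graph_from_edgelist count_components
#'   canonical_permutation add_vertices vcount
#' @importFrom stats kmeans rnorm runif cor sd plogis
#' @importFrom utils read.csv modifyList type.convert packageVersion
#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
"_PACKAGE"

## Evaluate an expression under a temporary RNG state.
## Saves and restores .Random.seed so library code never perturbs the
## caller's random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a component seed from a root seed
#'
#' A single root seed deterministically yields a distinct seed for every
#' named component of a run (clustering, masking, shuffling, ...), so one
#' integer reproduces a whole pipeline. The derivation is a polynomial
#' byte hash of the component name folded into the root seed, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param root integer root seed.
#' @param component character scalar naming the consumer, e.g. "mask".
#' @return a positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "mask")
derive_seed <- function(root, component) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(component))
  m <- 2147483647
  h <- as.double(root) %% m
  for (b in utf8ToInt(component)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1L) + 1)
}

## ceiling that is exact for the quota arithmetic used by the mask operator
.quota <- function(ratio, n) {
  if (ratio <= 0) return(0L)
  as.integer(ceiling(ratio * n - 1e-9))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
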