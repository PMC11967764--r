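## config: YAML run configuration, validation, derived seeds, manifests,
## and checkpoint (de)serialization for resumable runs.

.default_config <- function() list(
  seed = 1L,
  out_dir = ".",
  chem_io = list(keep_largest_fragment = TRUE),
  synth = list(n_molecules = 2000L, n_families = 8L,
               label_rule = "aromatic_ring", noise_sd = 0,
               subs_min = 0L, subs_max = 3L, ring_substituents = FALSE),
  augment = list(granularities = c(100L, 1000L, 10000L), mask_ratio = 0.25),
  encoder = list(n_layers = 5L, hidden_dim = 300L, graph_dim = 512L,
                 latent_dim = 256L),
  pretrain = list(epochs = 30L, batch_size = 256L, learning_rate = 1e-3,
                  mode = "full"),
  finetune = list(epochs = 60L, batch_size = 64L, learning_rate = 1e-3,
                  patience = 10L, split = "scaffold", task = "clf"),
  analysis = list(k = 5L, n_bins = 10L, per_bin = 1000L))

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), overlays it on the package
#' defaults, applies `key=value` overrides with dotted paths
#' (e.g. `"pretrain.epochs=5"`), and validates every section before any
#' work starts. Validation failures list every offending key.
#'
#' @param path YAML file path, a list, or `NULL` for pure defaults.
#' @param overrides character vector of `dotted.key=value` overrides.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = character(0)) {
  cfg <- .default_config()
  user <- if (is.null(path)) list()
    else if (is.list(path)) path
    else yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, user)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) .stopf("bad override '%s' (want key=value)", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg <- .assign_path(cfg, keys, val)
  }
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: one integer")
  chk(all(cfg$augment$granularities >= 2),
      "augment.granularities: every K must be >= 2")
  chk(cfg$augment$mask_ratio >= 0 && cfg$augment$mask_ratio <= 1,
      "augment.mask_ratio: must lie in [0, 1]")
  chk(cfg$encoder$n_layers >= 1, "encoder.n_layers: must be >= 1")
  chk(min(cfg$encoder$hidden_dim, cfg$encoder$graph_dim,
          cfg$encoder$latent_dim) >= 1, "encoder dims: must be >= 1")
  chk(cfg$pretrain$epochs >= 1, "pretrain.epochs: must be >= 1")
  chk(cfg$pretrain$mode %in% c("full", "mlct_only", "mcl_only", "none"),
      "pretrain.mode: one of full/mlct_only/mcl_only/none")
  chk(cfg$synth$n_molecules >= 1, "synth.n_molecules: must be >= 1")
  chk(cfg$finetune$split %in% c("scaffold", "random"),
      "finetune.split: scaffold or random")
  if (length(errs))
    .stopf("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

.assign_path <- function(lst, keys, val) {
  if (length(keys) == 1) { lst[[keys]] <- val; return(lst) }
  lst[[keys[1]]] <- .assign_path(lst[[keys[1]]] %||% list(), keys[-1], val)
  lst
}

#' Write a reproducibility manifest next to an artifact
#'
#' Records the configuration, root seed, package version and md5 digests
#' of the input files, so any artifact can be regenerated from its
#' manifest.
#'
#' @param artifact_path path of the artifact the manifest describes.
#' @param config the `run_config` used.
#' @param inputs character vector of input file paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(artifact_path, config, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man <- list(artifact = basename(artifact_path),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("molssl")),
              seed = config$seed,
              config = unclass(config),
              input_md5 = digests)
  path <- paste0(artifact_path, ".manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Save a pretrained model checkpoint
#'
#' Round-trips bit-exactly through [load_checkpoint()]: encoder config
#' and parameters, classifier heads, the fitted pseudo-labeler and the
#' training log.
#'
#' @param model an `mtss_model`.
#' @param path checkpoint file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mtss_model"))
  obj <- list(format_version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the restored `mtss_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L))
    .stopf("unsupported checkpoint format version")
  obj$model
}
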