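## synthdata: seeded generator of toy molecular corpora with latent
## structural families (one scaffold per family, random substituents) and
## structure-derived property labels, so every other module is testable
## without external downloads.

.SCAFFOLDS <- list(
  # tokens: per-position atom token; ring scaffolds close position 1 to the
  # last position; attach marks H-bearing positions that accept substituents.
  # Ordering alternates aromatic / non-aromatic so a prefix of the list
  # yields balanced aromatic labels.
  list(name = "benzene",         tokens = rep("c", 6), ring = TRUE,
       attach = rep(TRUE, 6),  aromatic = TRUE),
  list(name = "cyclohexane",     tokens = rep("C", 6), ring = TRUE,
       attach = rep(TRUE, 6),  aromatic = FALSE),
  list(name = "pyridine",        tokens = c("c","c","c","c","c","n"),
       ring = TRUE, attach = c(rep(TRUE, 5), FALSE), aromatic = TRUE),
  list(name = "piperidine",      tokens = c("C","C","C","C","C","N"),
       ring = TRUE, attach = c(rep(TRUE, 5), FALSE), aromatic = FALSE),
  list(name = "furan",           tokens = c("c","c","c","c","o"),
       ring = TRUE, attach = c(rep(TRUE, 4), FALSE), aromatic = TRUE),
  list(name = "tetrahydrofuran", tokens = c("C","C","C","C","O"),
       ring = TRUE, attach = c(rep(TRUE, 4), FALSE), aromatic = FALSE),
  list(name = "thiophene",       tokens = c("c","c","c","c","s"),
       ring = TRUE, attach = c(rep(TRUE, 4), FALSE), aromatic = TRUE),
  list(name = "tetrahydropyran", tokens = c("C","C","C","C","C","O"),
       ring = TRUE, attach = c(rep(TRUE, 5), FALSE), aromatic = FALSE),
  list(name = "pyrimidine",      tokens = c("c","n","c","n","c","c"),
       ring = TRUE, attach = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
       aromatic = TRUE),
  list(name = "cyclopentane",    tokens = rep("C", 5), ring = TRUE,
       attach = rep(TRUE, 5),  aromatic = FALSE),
  list(name = "pyrrole",         tokens = c("c","c","c","c","[nH]"),
       ring = TRUE, attach = c(rep(TRUE, 4), FALSE), aromatic = TRUE),
  list(name = "morpholine",      tokens = c("C","C","O","C","C","N"),
       ring = TRUE, attach = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
       aromatic = FALSE),
  list(name = "hexane",          tokens = rep("C", 6), ring = FALSE,
       attach = rep(TRUE, 6),  aromatic = FALSE),
  list(name = "diethyl_ether",   tokens = c("C","C","O","C","C"),
       ring = FALSE, attach = c(TRUE, TRUE, FALSE, TRUE, TRUE),
       aromatic = FALSE))

#' Default scaffold set of the synthetic generator
#'
#' Fourteen small scaffolds (aromatic and saturated rings, two chains),
#' ordered so the first `n` alternate aromatic / non-aromatic.
#' @return character vector of scaffold names.
#' @export
default_scaffolds <- function() vapply(.SCAFFOLDS, `[[`, "", "name")

#' Default substituent set of the synthetic generator
#'
#' Halogens, hydroxyl, methyl, amino and nitro groups, written as SMILES
#' branch bodies. `rings = TRUE` adds cycloalkyl substituents (cyclopropyl,
#' cyclobutyl), which extend the ring framework of the decorated molecule
#' and therefore create scaffold diversity for scaffold-split experiments.
#'
#' @param rings include cycloalkyl substituents.
#' @return named character vector of SMILES fragments.
#' @export
default_substituents <- function(rings = FALSE) {
  base <- c(fluoro = "F", chloro = "Cl", bromo = "Br", hydroxyl = "O",
            methyl = "C", amino = "N", nitro = "[N+](=O)[O-]")
  if (rings) base <- c(base, cyclopropyl = "C3CC3", cyclobutyl = "C3CCC3")
  base
}

#' Specification of a synthetic molecule corpus
#'
#' @param n_molecules corpus size.
#' @param n_families number of latent structural families; must not exceed
#'   the scaffold set size. Family `i` uses scaffold `i`.
#' @param scaffolds scaffold names, subset of [default_scaffolds()].
#' @param substituents named SMILES fragments, see [default_substituents()].
#' @param subs_range integer range (min, max) of substituents per molecule.
#' @param label_rule one of `"aromatic_ring"` (binary: any aromatic bond),
#'   `"heteroatom_count"` (binary: >= `hetero_threshold` non-carbon heavy
#'   atoms), `"size_hetero_linear"` (real: 0.5 * heavy atoms +
#'   1.5 * heteroatoms + Gaussian noise).
#' @param hetero_threshold threshold for the heteroatom rule.
#' @param noise_sd Gaussian noise standard deviation for regression rules.
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_molecules = 2000, n_families = 8,
                       scaffolds = default_scaffolds(),
                       substituents = default_substituents(),
                       subs_range = c(0L, 3L),
                       label_rule = "aromatic_ring",
                       hetero_threshold = 2L,
                       noise_sd = 0, seed = 1) {
  scaffolds <- match.arg(scaffolds, default_scaffolds(), several.ok = TRUE)
  if (n_families > length(scaffolds))
    .stopf("n_families (%d) exceeds scaffold set size (%d)",
           n_families, length(scaffolds))
  stopifnot(n_molecules >= 1, n_families >= 1, length(subs_range) == 2,
            subs_range[1] >= 0, subs_range[2] >= subs_range[1],
            noise_sd >= 0, length(substituents) >= 1)
  label_rule <- match.arg(label_rule, c("aromatic_ring", "heteroatom_count",
                                        "size_hetero_linear"))
  structure(list(n_molecules = as.integer(n_molecules),
                 n_families = as.integer(n_families),
                 scaffolds = scaffolds, substituents = substituents,
                 subs_range = as.integer(subs_range),
                 label_rule = label_rule,
                 hetero_threshold = as.integer(hetero_threshold),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

## assemble one decorated scaffold into a SMILES string
.assemble_smiles <- function(sc, branch_at) {
  k <- length(sc$tokens)
  parts <- character(k)
  for (p in seq_len(k)) {
    tok <- sc$tokens[p]
    ring_digit <- if (sc$ring && (p == 1L || p == k)) "1" else ""
    br <- if (!is.na(branch_at[p])) paste0("(", branch_at[p], ")") else ""
    parts[p] <- paste0(tok, ring_digit, br)
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic molecule corpus
#'
#' Each molecule is one family scaffold decorated with seeded random
#' substituents at random H-bearing positions. All emitted SMILES are
#' chemically valid by construction (attachment only where a hydrogen can
#' be replaced) and are canonicalized through the normal parsing path.
#'
#' @param spec a [synth_spec()].
#' @return list with `molecules` (list of `molecule`), `family` (integer
#'   family id per molecule), `family_name`, and `smiles` (canonical).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sc_by_name <- .SCAFFOLDS[match(spec$scaffolds, default_scaffolds())]
  fams <- sc_by_name[seq_len(spec$n_families)]
  with_local_seed(spec$seed, {
    family <- sample(rep_len(seq_len(spec$n_families), spec$n_molecules))
    smiles <- character(spec$n_molecules)
    for (i in seq_len(spec$n_molecules)) {
      sc <- fams[[family[i]]]
      open <- which(sc$attach)
      ns <- sample(seq(spec$subs_range[1], spec$subs_range[2]), 1)
      ns <- min(ns, length(open))
      branch <- rep(NA_character_, length(sc$tokens))
      if (ns > 0) {
        pos <- sample(open, ns)
        branch[pos] <- sample(spec$substituents, ns, replace = TRUE)
      }
      smiles[i] <- .assemble_smiles(sc, branch)
    }
    res <- parse_smiles_batch(smiles, quiet = TRUE)
    if (res$n_skipped > 0)
      .stopf("synthetic generator emitted %d invalid SMILES; this is a bug",
             res$n_skipped)
    list(molecules = res$molecules, family = family,
         family_name = vapply(fams, `[[`, "", "name")[family],
         smiles = vapply(res$molecules, function(m) m$smiles, ""))
  })
}

#' Compute labels for a corpus from a structural rule
#'
#' Classification rules emit \{0, 1\}; the regression rule emits reals with
#' optional additive Gaussian noise. Noiseless rules are exactly
#' recoverable from molecular structure, so fine-tuning has a known oracle.
#'
#' @param corpus output of [generate_corpus()], or a list of `molecule`.
#' @param label_rule,hetero_threshold,noise_sd,seed see [synth_spec()].
#' @return numeric vector of labels with attribute `task_type`
#'   (`"classification"` or `"regression"`).
#' @export
generate_labels <- function(corpus, label_rule = "aromatic_ring",
                            hetero_threshold = 2L, noise_sd = 0, seed = 1) {
  mols <- if (!is.null(corpus$molecules)) corpus$molecules else corpus
  label_rule <- match.arg(label_rule, c("aromatic_ring", "heteroatom_count",
                                        "size_hetero_linear"))
  graphs <- lapply(mols, `[[`, "graph")
  y <- switch(label_rule,
    aromatic_ring = vapply(graphs, function(g)
      as.numeric(any(g$bond_type == BOND_TYPE_CODES[["aromatic"]])), 0),
    heteroatom_count = vapply(graphs, function(g)
      as.numeric(sum(g$atomic_number != 6L) >= hetero_threshold), 0),
    size_hetero_linear = vapply(graphs, function(g)
      0.5 * g$n_atoms + 1.5 * sum(g$atomic_number != 6L), 0))
  task <- if (label_rule == "size_hetero_linear") "regression"
          else "classification"
  if (task == "regression" && noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  structure(y, task_type = task)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> n=%d, %d families, %d substituents, rule=%s, seed=%d\n",
    x$n_molecules, x$n_families, length(x$substituents), x$label_rule,
    x$seed))
  invisible(x)
}
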