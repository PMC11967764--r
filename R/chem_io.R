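## chem_io: SMILES -> attributed molecular graphs, MACCS fingerprints,
## physicochemical descriptors, corpus file I/O.
##
## Validation, canonicalization, MACCS keys and scalar descriptors are
## delegated to OpenBabel (obabel, called in batch). Graph extraction is
## done by an in-package reader of OpenBabel canonical SMILES, because the
## encoder needs aromaticity, chirality and bond-direction features that do
## not survive OpenBabel's kekulized SDF output.

# ---------------------------------------------------------------------------
# element table and vocabularies

.ELEMENTS <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og")

#' Chirality codes used in atom features
#'
#' Fixed 4-value vocabulary: 1 unspecified, 2 clockwise, 3 counter-clockwise,
#' 4 other (extended stereo descriptors).
#' @export
CHIRALITY_CODES <- c(unspecified = 1L, clockwise = 2L,
                     counter_clockwise = 3L, other = 4L)

#' Bond type codes used in bond features
#' @export
BOND_TYPE_CODES <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

#' Bond direction codes used in bond features
#'
#' SMILES cis/trans markers: 1 none, 2 end-upward ("/"), 3 end-downward ("\\").
#' @export
BOND_DIR_CODES <- c(none = 1L, end_upward = 2L, end_downward = 3L)

# ---------------------------------------------------------------------------
# obabel plumbing

.check_obabel <- local({
  seen <- FALSE
  function() {
    if (!seen) {
      if (Sys.which("obabel") == "")
        .stopf("obabel executable not found on PATH; install OpenBabel")
      seen <<- TRUE
    }
    invisible(TRUE)
  }
})

## Run obabel over a batch of SMILES, one per line, titled i<row>.
## Returns the raw stdout lines; molecules obabel fails on are absent and
## are realigned by the caller via titles.
.ob_batch <- function(smiles, args) {
  .check_obabel()
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile))
  writeLines(paste(smiles, paste0("i", seq_along(smiles))), infile)
  suppressWarnings(system2("obabel", c(infile, args),
                           stdout = TRUE, stderr = FALSE))
}

## Light syntactic screen applied before OpenBabel, which silently "repairs"
## inputs such as "C(" -> "C". Checks: legal characters, balanced () and [],
## paired ring-closure labels, no leading/dangling bond token.
.smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("\\s", s)) return(FALSE)
  if (grepl("[^A-Za-z0-9\\[\\]()=#:+\\\\/@%.*-]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; brk <- FALSE
  open_rings <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (brk) { if (ch == "]") brk <- FALSE; i <- i + 1L; next }
    if (ch == "[") { brk <- TRUE }
    else if (ch == "]") return(FALSE)
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0) return(FALSE) }
    else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i+1L], chars[i+2L])))
        return(FALSE)
      lab <- paste0("%", chars[i+1L], chars[i+2L])
      open_rings <- if (lab %in% open_rings) setdiff(open_rings, lab)
                    else c(open_rings, lab)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      open_rings <- if (ch %in% open_rings) setdiff(open_rings, ch)
                    else c(open_rings, ch)
    }
    i <- i + 1L
  }
  if (brk || depth != 0L || length(open_rings) > 0L) return(FALSE)
  # a bond symbol must not end the string
  if (grepl("[-=#:/\\\\]$", s)) return(FALSE)
  TRUE
}

#' Canonicalize SMILES strings
#'
#' Validates syntax, then canonicalizes through OpenBabel in one batched
#' call. Multi-fragment inputs (salts, mixtures) are reduced to their
#' largest fragment by heavy-atom count, then re-canonicalized.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- vapply(smiles, .smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (!any(ok)) return(out)
  res <- .ob_batch(smiles[ok], "-ocan")
  res <- res[grepl("\ti[0-9]+\\s*$", res)]
  if (length(res)) {
    parts <- strsplit(res, "\t")
    can <- vapply(parts, `[`, "", 1L)
    idx <- as.integer(sub("^i", "", trimws(vapply(parts, `[`, "", 2L))))
    out[which(ok)[idx]] <- can
  }
  # keep the largest fragment of multi-fragment results
  multi <- which(!is.na(out) & grepl(".", out, fixed = TRUE))
  if (length(multi)) {
    best <- vapply(out[multi], function(s) {
      frags <- strsplit(s, ".", fixed = TRUE)[[1]]
      sizes <- vapply(frags, function(f)
        tryCatch(.parse_smiles_graph(f)$n_atoms, error = function(e) -1L),
        integer(1))
      frags[which.max(sizes)]
    }, character(1))
    redo <- .ob_batch(best, "-ocan")
    redo <- redo[grepl("\ti[0-9]+\\s*$", redo)]
    out[multi] <- NA_character_
    if (length(redo)) {
      parts <- strsplit(redo, "\t")
      can <- vapply(parts, `[`, "", 1L)
      idx <- as.integer(sub("^i", "", trimws(vapply(parts, `[`, "", 2L))))
      out[multi[idx]] <- can
    }
  }
  out
}

# ---------------------------------------------------------------------------
# canonical-SMILES -> attributed graph

## Tokenize and parse one single-fragment SMILES string into an attributed
## graph. Handles the organic subset, bracket atoms (isotope, chirality,
## H count, charge, atom map), aromatic lowercase atoms, branches, ring
## closures (including %nn), and bond symbols - = # : / \.
.parse_smiles_graph <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  z <- integer(0); chir <- integer(0); arom <- logical(0)
  eu <- integer(0); ev <- integer(0); et <- integer(0); ed <- integer(0)
  prev <- 0L                      # index of the previous atom
  stack <- integer(0)             # branch stack
  pend_bond <- NA_character_      # explicit bond symbol awaiting next atom
  rings <- list()                 # label -> list(atom, bond)
  sym2z <- function(sym) {
    iz <- match(sym, .ELEMENTS)
    if (is.na(iz)) .stopf("unknown element symbol '%s' in SMILES '%s'", sym, s)
    iz
  }
  add_atom <- function(zi, aromatic, chirality) {
    z[length(z) + 1L] <<- zi
    arom[length(arom) + 1L] <<- aromatic
    chir[length(chir) + 1L] <<- chirality
    length(z)
  }
  bond_code <- function(sym, a, b) {
    if (is.na(sym)) {
      ty <- if (arom[a] && arom[b]) BOND_TYPE_CODES[["aromatic"]]
            else BOND_TYPE_CODES[["single"]]
      c(ty, BOND_DIR_CODES[["none"]])
    } else {
      switch(sym,
        "-"  = c(BOND_TYPE_CODES[["single"]],  BOND_DIR_CODES[["none"]]),
        "="  = c(BOND_TYPE_CODES[["double"]],  BOND_DIR_CODES[["none"]]),
        "#"  = c(BOND_TYPE_CODES[["triple"]],  BOND_DIR_CODES[["none"]]),
        ":"  = c(BOND_TYPE_CODES[["aromatic"]],BOND_DIR_CODES[["none"]]),
        "/"  = c(BOND_TYPE_CODES[["single"]],  BOND_DIR_CODES[["end_upward"]]),
        "\\" = c(BOND_TYPE_CODES[["single"]],  BOND_DIR_CODES[["end_downward"]]),
        .stopf("unsupported bond symbol '%s'", sym))
    }
  }
  add_bond <- function(a, b, sym) {
    force(a); force(b); force(sym)
    tb <- bond_code(sym, a, b)
    eu[length(eu) + 1L] <<- min(a, b)
    ev[length(ev) + 1L] <<- max(a, b)
    et[length(et) + 1L] <<- tb[1L]
    ed[length(ed) + 1L] <<- tb[2L]
  }
  connect <- function(idx) {
    force(idx)   # append the atom before any bond bookkeeping reads state
    if (prev > 0L) add_bond(prev, idx, pend_bond)
    pend_bond <<- NA_character_
    prev <<- idx
  }
  ring_event <- function(lab) {
    if (prev == 0L) .stopf("ring closure before any atom in '%s'", s)
    if (!is.null(rings[[lab]])) {
      op <- rings[[lab]]
      sym <- if (!is.na(pend_bond)) pend_bond else op$bond
      add_bond(op$atom, prev, sym)
      rings[[lab]] <<- NULL
      pend_bond <<- NA_character_
    } else {
      rings[[lab]] <<- list(atom = prev, bond = pend_bond)
      pend_bond <<- NA_character_
    }
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .stopf("unterminated bracket atom in '%s'", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([[:alpha:]][[:lower:]]?)(@@?|@[[:upper:]]{2}[0-9]+|)(H[0-9]*)?([+-]+[0-9]*|[+-]?)([:][0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) .stopf("cannot parse bracket atom [%s]", body)
      sym <- m[3]
      aromatic <- sym %in% c("b","c","n","o","p","s","se","as")
      zi <- sym2z(if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym)
      chs <- m[4]
      chirality <- if (chs == "@") CHIRALITY_CODES[["counter_clockwise"]]
        else if (chs == "@@") CHIRALITY_CODES[["clockwise"]]
        else if (nzchar(chs)) CHIRALITY_CODES[["other"]]
        else CHIRALITY_CODES[["unspecified"]]
      connect(add_atom(zi, aromatic, chirality))
      i <- j + 1L
      next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- ch; i <- i + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) .stopf("unbalanced ')' in '%s'", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == "%") {
      if (i + 2L > n) .stopf("bad %% ring label in '%s'", s)
      ring_event(paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L; next
    }
    if (ch %in% as.character(0:9)) { ring_event(ch); i <- i + 1L; next }
    if (ch == ".") .stopf("multi-fragment SMILES reached graph parser: '%s'", s)
    if (ch %in% LETTERS) {
      sym <- ch
      if (i < n && chars[i + 1L] %in% letters &&
          paste0(ch, chars[i + 1L]) %in% .ELEMENTS &&
          # two-letter organic-subset elements outside brackets: Cl and Br only
          paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
        sym <- paste0(ch, chars[i + 1L]); i <- i + 1L
      }
      connect(add_atom(sym2z(sym), FALSE, CHIRALITY_CODES[["unspecified"]]))
      i <- i + 1L; next
    }
    if (ch %in% letters) {
      if (!ch %in% c("b", "c", "n", "o", "p", "s"))
        .stopf("invalid aromatic atom '%s' in '%s'", ch, s)
      connect(add_atom(sym2z(toupper(ch)), TRUE,
                       CHIRALITY_CODES[["unspecified"]]))
      i <- i + 1L; next
    }
    .stopf("unexpected character '%s' in SMILES '%s'", ch, s)
  }
  if (length(rings)) .stopf("unmatched ring closure in '%s'", s)
  if (length(stack)) .stopf("unbalanced '(' in '%s'", s)
  if (length(z) == 0L) .stopf("SMILES '%s' contains no atoms", s)
  new_mol_graph(z, chir, arom, cbind(eu, ev), et, ed)
}

#' Construct a molecular graph object
#'
#' The unit of all computation downstream: heavy-atom nodes carrying atomic
#' number and chirality, undirected bonds carrying type and direction.
#' Edges are stored once with `u < v`; an adjacency list is derived.
#'
#' @param atomic_number integer vector (>= 1) per node.
#' @param chirality integer codes, see [CHIRALITY_CODES]; 0 is reserved for
#'   the mask token used during contrastive pretraining.
#' @param aromatic logical per node.
#' @param edges two-column integer matrix of node indices.
#' @param bond_type,bond_dir integer codes per edge, see [BOND_TYPE_CODES]
#'   and [BOND_DIR_CODES].
#' @return an object of class `mol_graph`.
#' @export
new_mol_graph <- function(atomic_number, chirality, aromatic, edges,
                          bond_type, bond_dir) {
  n <- length(atomic_number)
  stopifnot(n >= 1L, length(chirality) == n, length(aromatic) == n)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    stopifnot(all(edges >= 1L), all(edges <= n),
              all(edges[, 1] < edges[, 2]),
              length(bond_type) == nrow(edges),
              length(bond_dir) == nrow(edges))
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
    adj <- lapply(adj, sort)
  }
  structure(list(
    n_atoms = n,
    atomic_number = as.integer(atomic_number),
    chirality = as.integer(chirality),
    aromatic = as.logical(aromatic),
    edges = edges,
    bond_type = as.integer(bond_type),
    bond_dir = as.integer(bond_dir),
    adjacency = adj), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds (%d aromatic)\n",
              x$n_atoms, nrow(x$edges),
              sum(x$bond_type == BOND_TYPE_CODES[["aromatic"]])))
  invisible(x)
}

#' Parse a SMILES string into a molecule
#'
#' Validates and canonicalizes through OpenBabel, then extracts the
#' heavy-atom attributed graph. Invalid SMILES raise an error; use
#' [read_corpus()] for skip-and-log semantics over files.
#'
#' @param smiles a single SMILES string.
#' @param id optional identifier carried with the molecule.
#' @return an object of class `molecule` with fields `id`, `smiles`
#'   (canonical) and `graph` (a [new_mol_graph()] object).
#' @export
#' @examples
#' \dontrun{
#' m <- parse_smiles("CCO")
#' m$graph$n_atoms  # 3
#' }
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) .stopf("invalid SMILES: '%s'", smiles)
  structure(list(id = id, smiles = can, graph = .parse_smiles_graph(can)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s  %s  (%d atoms)\n", x$id, x$smiles,
              x$graph$n_atoms))
  invisible(x)
}

#' Parse a vector of SMILES, skipping invalid entries
#'
#' @param smiles character vector.
#' @param ids identifiers (default sequential).
#' @param quiet suppress the skip warning.
#' @return list with `molecules` (list of `molecule`), `n_skipped`, and
#'   `skipped` (indices of dropped inputs).
#' @export
parse_smiles_batch <- function(smiles, ids = NULL, quiet = FALSE) {
  stopifnot(is.character(smiles))
  if (is.null(ids)) ids <- sprintf("mol%05d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  can <- canonicalize_smiles(smiles)
  keep <- which(!is.na(can))
  mols <- vector("list", length(keep))
  ok <- logical(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    g <- tryCatch(.parse_smiles_graph(can[i]), error = function(e) NULL)
    if (!is.null(g)) {
      mols[[j]] <- structure(list(id = ids[i], smiles = can[i], graph = g),
                             class = "molecule")
      ok[j] <- TRUE
    }
  }
  mols <- mols[ok]
  skipped <- setdiff(seq_along(smiles), keep[ok])
  if (length(skipped) && !quiet)
    .warnf("skipped %d invalid SMILES (rows: %s)", length(skipped),
           paste(utils::head(skipped, 10), collapse = ", "))
  list(molecules = mols, n_skipped = length(skipped), skipped = skipped)
}

# ---------------------------------------------------------------------------
# fingerprints

#' Compute MACCS structural-key fingerprints
#'
#' 166-bit binary structural keys computed by OpenBabel's MACCS SMARTS
#' dictionary, the fingerprint used to build clustering pseudo-labels.
#'
#' @param mol a `molecule`, a list of molecules, or a character vector of
#'   SMILES (canonicalized internally).
#' @return for a single molecule an integer vector of length 166 with
#'   entries in \{0, 1\}; otherwise a matrix with one row per molecule.
#' @export
compute_maccs <- function(mol) {
  single <- inherits(mol, "molecule") ||
    (is.character(mol) && length(mol) == 1L)
  smi <- if (inherits(mol, "molecule")) mol$smiles
    else if (is.list(mol)) vapply(mol, function(m) m$smiles, "")
    else canonicalize_smiles(mol)
  if (anyNA(smi)) .stopf("invalid SMILES passed to compute_maccs")
  res <- .ob_batch(smi, c("-ofps", "-xfMACCS"))
  res <- res[!grepl("^#", res) & grepl("\t", res)]
  parts <- strsplit(res, "\t")
  hex <- vapply(parts, `[`, "", 1L)
  idx <- as.integer(sub("^i", "", trimws(vapply(parts, `[`, "", 2L))))
  if (length(idx) != length(smi))
    .stopf("fingerprint computation failed for %d molecules",
           length(smi) - length(idx))
  bits <- matrix(0L, length(smi), 166)
  lut <- .hex_bits_lut()
  for (r in seq_along(idx)) {
    pairs <- substring(hex[r], seq(1, nchar(hex[r]) - 1, 2),
                       seq(2, nchar(hex[r]), 2))
    b <- as.vector(vapply(pairs, function(p) lut[[p]], integer(8)))
    bits[idx[r], ] <- b[1:166]
  }
  if (single) bits[1, ] else bits
}

.hex_bits_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      # index by the byte value written as two lowercase hex chars
      vals <- lapply(0:255, function(v) as.integer(bitwAnd(v, 2^(0:7)) > 0))
      names(vals) <- sprintf("%02x", 0:255)
      lut <<- vals
    }
    lut
  }
})

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits; defined as 1 when both vectors are
#' all-zero.
#'
#' @param a,b binary vectors of equal length (166 for MACCS keys).
#' @return a real number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) .stopf("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# ---------------------------------------------------------------------------
# descriptors

#' Compute physicochemical descriptors
#'
#' MolLogP, MolWt (implicit hydrogens included), TPSA and rotatable-bond
#' count come from OpenBabel. QED is an in-package drug-likeness score in
#' `[0, 1]`: the geometric mean of trapezoidal desirability functions over
#' MW, logP, H-bond donors/acceptors, TPSA, rotatable bonds and aromatic
#' ring count. SA is an in-package synthetic-accessibility proxy in
#' `[1, 10]` from molecule size, ring rank and heteroatom fraction. Both
#' are deterministic; neither claims numerical equality with other
#' toolkits' implementations.
#'
#' @param mol a `molecule` or list of molecules.
#' @return a data.frame with columns `mol_logp`, `mol_wt`, `tpsa`,
#'   `num_rotatable_bonds`, `qed`, `sa` (one row per molecule). Descriptor
#'   failures surface as `NA`, never as an error.
#' @export
compute_descriptors <- function(mol) {
  mols <- if (inherits(mol, "molecule")) list(mol) else mol
  smi <- vapply(mols, function(m) m$smiles, "")
  res <- .ob_batch(smi, c("-osmi", "--append", "logP TPSA MW rotors HBA1 HBD abonds"))
  res <- res[grepl("\t", res)]
  n <- length(smi)
  out <- data.frame(mol_logp = rep(NA_real_, n), mol_wt = NA_real_,
                    tpsa = NA_real_, num_rotatable_bonds = NA_real_,
                    qed = NA_real_, sa = NA_real_)
  hba <- hbd <- abonds <- rep(NA_real_, n)
  for (line in res) {
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 2) next
    tv <- strsplit(trimws(f[2]), "\\s+")[[1]]
    i <- suppressWarnings(as.integer(sub("^i", "", tv[1])))
    if (is.na(i) || length(tv) < 8) next
    v <- suppressWarnings(as.numeric(tv[2:8]))
    out$mol_logp[i] <- v[1]; out$tpsa[i] <- v[2]; out$mol_wt[i] <- v[3]
    out$num_rotatable_bonds[i] <- v[4]
    hba[i] <- v[5]; hbd[i] <- v[6]; abonds[i] <- v[7]
  }
  for (i in seq_len(n)) {
    g <- mols[[i]]$graph
    narom_ring <- .cycle_rank(g, aromatic_only = TRUE)
    ring_rank <- .cycle_rank(g, aromatic_only = FALSE)
    het <- sum(g$atomic_number != 6L) / g$n_atoms
    out$qed[i] <- .qed_score(out$mol_wt[i], out$mol_logp[i], hba[i], hbd[i],
                             out$tpsa[i], out$num_rotatable_bonds[i],
                             narom_ring)
    out$sa[i] <- min(10, max(1, 1 + g$n_atoms / 12 + 0.8 * ring_rank +
                               2 * het))
  }
  rownames(out) <- vapply(mols, function(m) m$id, "")
  out
}

## number of independent cycles (SSSR count) of the (optionally aromatic)
## bond subgraph: edges - nodes + components
.cycle_rank <- function(g, aromatic_only = FALSE) {
  keep <- if (aromatic_only) g$bond_type == BOND_TYPE_CODES[["aromatic"]]
          else rep(TRUE, length(g$bond_type))
  e <- g$edges[keep, , drop = FALSE]
  if (!nrow(e)) return(0L)
  verts <- sort(unique(as.vector(e)))
  ig <- igraph::graph_from_edgelist(
    matrix(match(as.vector(e), verts), ncol = 2), directed = FALSE)
  nrow(e) - length(verts) + igraph::count_components(ig)
}

## trapezoid in [0,1]: 0 outside (lo0, hi0), 1 inside [lo1, hi1]
.trap <- function(x, lo0, lo1, hi1, hi0) {
  if (is.na(x)) return(NA_real_)
  if (x <= lo0 || x >= hi0) return(0.001)   # floor avoids zero geometric mean
  if (x >= lo1 && x <= hi1) return(1)
  if (x < lo1) (x - lo0) / (lo1 - lo0) else (hi0 - x) / (hi0 - hi1)
}

.qed_score <- function(mw, logp, hba, hbd, tpsa, rotb, arom) {
  d <- c(.trap(mw,   60, 160, 480, 800),
         .trap(logp, -4,   0,   4,   8),
         .trap(hba,  -1,   0,  10,  16),
         .trap(hbd,  -1,   0,   5,  10),
         .trap(tpsa, -1,  20, 130, 250),
         .trap(rotb, -1,   0,  10,  18),
         .trap(arom, -1,   0,   3,   6))
  if (anyNA(d)) return(NA_real_)
  exp(mean(log(pmax(d, 1e-3))))
}

# ---------------------------------------------------------------------------
# corpus I/O

#' Read a SMILES corpus from disk
#'
#' `.smi` files hold one SMILES per line with an optional
#' whitespace-separated identifier; `.csv` files need a SMILES column.
#' Invalid rows are skipped with a warning and counted.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"smi"` or `"csv"`.
#' @param smiles_column CSV column holding SMILES.
#' @param id_column optional CSV column holding identifiers.
#' @return list with `molecules`, `n_skipped`, `skipped`, and for CSV input
#'   `table` (the remaining columns for the kept rows, e.g. labels).
#' @export
read_corpus <- function(path, format = c("auto", "smi", "csv"),
                        smiles_column = "smiles", id_column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) .stopf("empty corpus: %s", path)
    parts <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%05d", i), "")
    if (anyDuplicated(ids)) ids <- make.unique(ids)
    res <- parse_smiles_batch(smi, ids)
    tab <- NULL
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_column %in% names(df))
      .stopf("column '%s' not found in %s", smiles_column, path)
    if (!nrow(df)) .stopf("empty corpus: %s", path)
    ids <- if (!is.null(id_column) && id_column %in% names(df))
      as.character(df[[id_column]]) else sprintf("mol%05d", seq_len(nrow(df)))
    if (anyDuplicated(ids)) ids <- make.unique(ids)
    res <- parse_smiles_batch(df[[smiles_column]], ids)
    keep <- setdiff(seq_len(nrow(df)), res$skipped)
    tab <- df[keep, setdiff(names(df), smiles_column), drop = FALSE]
  }
  if (!length(res$molecules)) .stopf("empty corpus after filtering: %s", path)
  c(res, list(table = tab))
}

#' Write a fingerprint table
#'
#' Columnar plain-text serialization: id, canonical SMILES, 166-character
#' bit string, tab-separated.
#'
#' @param molecules list of `molecule` objects.
#' @param fingerprints matrix from [compute_maccs()].
#' @param path output path.
#' @export
write_fingerprint_table <- function(molecules, fingerprints, path) {
  stopifnot(length(molecules) == nrow(fingerprints))
  lines <- vapply(seq_along(molecules), function(i)
    paste(molecules[[i]]$id, molecules[[i]]$smiles,
          paste(fingerprints[i, ], collapse = ""), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
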