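# SMILES parsing, fingerprints, descriptors, corpus I/O

test_that("parse_smiles builds correct heavy-atom graphs", {
  m <- parse_smiles("CCO")
  expect_identical(m$graph$n_atoms, 3L)
  expect_identical(nrow(m$graph$edges), 2L)
  ring <- parse_smiles("C1CC1")
  expect_identical(ring$graph$n_atoms, 3L)
  expect_identical(nrow(ring$graph$edges), 3L)
  expect_error(parse_smiles("C("), "invalid SMILES")
  expect_error(parse_smiles("C1CC"), "invalid SMILES")
  expect_error(parse_smiles("CX"), "invalid SMILES")
})

test_that("aromatic perception and feature vocabularies are respected", {
  b <- parse_smiles("c1ccccc1")
  expect_identical(sum(b$graph$bond_type == BOND_TYPE_CODES[["aromatic"]]), 6L)
  expect_true(all(b$graph$chirality %in% CHIRALITY_CODES))
  expect_true(all(b$graph$bond_dir %in% BOND_DIR_CODES))
  chi <- parse_smiles("C[C@H](N)O")
  expect_true(any(chi$graph$chirality %in%
                    CHIRALITY_CODES[c("clockwise", "counter_clockwise")]))
  cis <- parse_smiles("F/C=C/F")
  expect_true(any(cis$graph$bond_dir != BOND_DIR_CODES[["none"]]))
})

test_that("kekulized and aromatic SMILES of one molecule canonicalize equally", {
  expect_identical(canonicalize_smiles("c1ccccc1"),
                   canonicalize_smiles("C1=CC=CC=C1"))
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
})

test_that("multi-fragment SMILES keep the largest fragment", {
  m <- parse_smiles("CCO.[Na]")
  expect_identical(m$graph$n_atoms, 3L)
  expect_identical(m$smiles, canonicalize_smiles("CCO"))
})

test_that("round-trip parse -> canonical -> parse preserves graph structure", {
  co <- fixture_corpus()
  for (m in co$molecules[seq(1, 240, by = 12)]) {
    m2 <- parse_smiles(m$smiles)
    expect_identical(m2$graph$n_atoms, m$graph$n_atoms)
    expect_identical(nrow(m2$graph$edges), nrow(m$graph$edges))
    expect_identical(degree_multiset(m2$graph), degree_multiset(m$graph))
    expect_identical(sort(m2$graph$atomic_number), sort(m$graph$atomic_number))
  }
})

test_that("graph reader agrees with the toolkit's atom and bond counts", {
  # independent oracle: OpenBabel's own atoms/bonds descriptors
  co <- fixture_corpus()
  smi <- co$smiles[seq(1, 240, by = 8)]
  infile <- tempfile(fileext = ".smi")
  writeLines(smi, infile)
  out <- suppressWarnings(system2(
    "obabel", c(infile, "-osmi", "--append", "'atoms bonds'"),
    stdout = TRUE, stderr = FALSE))
  out <- out[grepl("\t", out)]
  counts <- do.call(rbind, lapply(out, function(l)
    as.integer(strsplit(trimws(strsplit(l, "\t")[[1]][2]), "\\s+")[[1]])))
  expect_identical(nrow(counts), length(smi))
  for (i in seq_along(smi)) {
    g <- parse_smiles(smi[i])$graph
    expect_identical(g$n_atoms, counts[i, 1])
    expect_identical(nrow(g$edges), counts[i, 2])
  }
})

test_that("MACCS fingerprints are 166-bit binary and deterministic", {
  fp <- compute_maccs(parse_smiles("c1ccccc1"))
  expect_length(fp, 166)
  expect_true(all(fp %in% c(0L, 1L)))
  fp2 <- compute_maccs(parse_smiles("C1=CC=CC=C1"))
  expect_identical(fp, fp2)
  # a single carbon sets strictly fewer structural keys than benzene
  expect_lt(sum(compute_maccs(parse_smiles("C"))), sum(fp))
})

test_that("tanimoto follows the set-overlap definition", {
  x <- integer(166); x[1:8] <- 1L
  expect_identical(tanimoto(x, x), 1)
  y <- integer(166); y[9:16] <- 1L
  expect_identical(tanimoto(x, y), 0)
  a <- integer(166); a[c(1, 2)] <- 1L
  b <- integer(166); b[c(1, 3)] <- 1L
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_identical(tanimoto(integer(166), integer(166)), 1)
  expect_error(tanimoto(x, x[-1]), "mismatch")
  # symmetry over random pairs
  set.seed(9)
  for (i in 1:20) {
    u <- rbinom(166, 1, 0.2); v <- rbinom(166, 1, 0.2)
    expect_identical(tanimoto(u, v), tanimoto(v, u))
  }
})

test_that("descriptors match conventional definitions and ranges", {
  d <- compute_descriptors(list(parse_smiles("CCO"), parse_smiles("C"),
                                parse_smiles("c1ccccc1")))
  # ethanol molecular weight: 2 C + 6 H + 1 O standard atomic masses
  expect_equal(d$mol_wt[1], 46.07, tolerance = 1e-3)
  expect_identical(d$num_rotatable_bonds[2], 0)
  expect_true(all(d$qed >= 0 & d$qed <= 1))
  expect_true(all(d$mol_wt > 0))
  expect_true(all(d$sa >= 1 & d$sa <= 10))
  # determinism
  d2 <- compute_descriptors(list(parse_smiles("CCO"), parse_smiles("C"),
                                 parse_smiles("c1ccccc1")))
  expect_identical(d, d2)
})

test_that("read_corpus handles smi and csv files with skip-and-log", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "c1ccccc1 benz", "C1CC1 cp"), smi)
  co <- read_corpus(smi)
  expect_length(co$molecules, 3)
  expect_identical(co$n_skipped, 0L)
  expect_identical(co$molecules[[1]]$id, "eth")

  bad <- tempfile(fileext = ".smi")
  writeLines(c("CCO", "C(", "CCN"), bad)
  expect_warning(co2 <- read_corpus(bad), "skipped 1")
  expect_length(co2$molecules, 2)
  expect_identical(co2$n_skipped, 1L)

  empty <- tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_error(read_corpus(empty), "empty corpus")

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCO", "CCN"), label = c(1, 0)), csv,
            row.names = FALSE)
  co3 <- read_corpus(csv)
  expect_length(co3$molecules, 2)
  expect_equal(co3$table$label, c(1, 0))
  expect_error(read_corpus(csv, smiles_column = "nope"), "not found")
  expect_error(read_corpus(tempfile()), "file not found")
})

test_that("fingerprint tables serialize as id/smiles/bitstring", {
  mols <- list(parse_smiles("CCO", id = "a"), parse_smiles("CCN", id = "b"))
  fp <- compute_maccs(mols)
  path <- tempfile()
  write_fingerprint_table(mols, fp, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_identical(f[1], "a")
  expect_identical(nchar(f[3]), 166L)
  expect_identical(as.integer(strsplit(f[3], "")[[1]]), as.integer(fp[1, ]))
})
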