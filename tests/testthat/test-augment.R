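# pseudo-labeling and graph masking

test_that("k-means separates well-separated fingerprint blobs optimally", {
  # independent oracle: with two far-apart duplicate blobs the optimal
  # 2-partition is the blob assignment (within-cluster SS = 0)
  blob1 <- matrix(rep(c(rep(1, 12), rep(0, 154)), 10), 10, byrow = TRUE)
  blob2 <- matrix(rep(c(rep(0, 154), rep(1, 12)), 10), 10, byrow = TRUE)
  x <- rbind(blob1, blob2)
  mdl <- fit_pseudo_labeler(x, 2L, seed = 5)
  lab <- assign_pseudo_labels(mdl, x)[, 1]
  expect_length(unique(lab[1:10]), 1)
  expect_length(unique(lab[11:20]), 1)
  expect_false(lab[1] == lab[11])
})

test_that("duplicate fingerprints share labels at every granularity", {
  set.seed(3)
  x <- matrix(rbinom(40 * 166, 1, 0.15), 40)
  x[40, ] <- x[1, ]    # duplicate
  mdl <- fit_pseudo_labeler(x, c(2L, 4L), seed = 8)
  lab <- assign_pseudo_labels(mdl, x)
  expect_identical(lab[1, ], lab[40, ])
  expect_identical(ncol(lab), 2L)
  expect_true(all(lab[, 1] >= 0 & lab[, 1] < 2))
  expect_true(all(lab[, 2] >= 0 & lab[, 2] < 4))
})

test_that("assignment ties break to the lowest centroid index", {
  mdl <- structure(list(
    granularities = 2L,
    centroids = list(rbind(rep(0, 166), rep(0, 166))),  # equidistant
    seed = 1L, n = 2L), class = "pseudo_labeler")
  fp <- rbinom(166, 1, 0.5)
  expect_identical(assign_pseudo_labels(mdl, fp)[[1]], 0L)
})

test_that("oversized granularities raise a named error", {
  x <- matrix(rbinom(5 * 166, 1, 0.2), 5)
  expect_error(fit_pseudo_labeler(x, c(2L, 10L), seed = 1), "K=10")
  expect_error(fit_pseudo_labeler(x, 1L, seed = 1), "below 2")
})

test_that("pseudo-labeling is deterministic in (corpus, granularities, seed)", {
  set.seed(6)
  x <- matrix(rbinom(60 * 166, 1, 0.2), 60)
  l1 <- assign_pseudo_labels(fit_pseudo_labeler(x, c(3L, 5L), seed = 9), x)
  l2 <- assign_pseudo_labels(fit_pseudo_labeler(x, c(3L, 5L), seed = 9), x)
  expect_identical(l1, l2)
})

test_that("mask quota is exactly ceil(ratio * n_atoms)", {
  co <- fixture_corpus()
  graphs <- lapply(co$molecules, `[[`, "graph")
  set.seed(12)
  for (i in 1:300) {
    g <- graphs[[sample(length(graphs), 1)]]
    ratio <- runif(1)
    mg <- mask_graph(g, ratio, seed = i)
    expect_identical(length(mg$masked_nodes), as.integer(ceiling(ratio * g$n_atoms - 1e-9)))
  }
  g <- graphs[[1]]
  expect_identical(length(mask_graph(g, 0, seed = 1)$masked_nodes), 0L)
  mg1 <- mask_graph(g, 1, seed = 1)
  expect_identical(length(mg1$masked_nodes), g$n_atoms)
  expect_identical(length(mg1$removed_edges), nrow(g$edges))
})

test_that("masked atoms grown from one start form a connected region", {
  path10 <- parse_smiles("CCCCCCCCCC")$graph
  mg <- mask_graph(path10, 0.3, seed = 2)
  m <- sort(mg$masked_nodes)
  expect_length(m, 3)
  # a path's connected induced subgraph is a contiguous index range
  expect_identical(m, seq(min(m), max(m)))
  # removed bonds are exactly the interior bonds of the masked segment
  expect_identical(length(mg$removed_edges), 2L)
  # both endpoints of every removed bond are masked
  for (e in mg$removed_edges)
    expect_true(all(path10$edges[e, ] %in% m))
})

test_that("masking is deterministic and seed-sensitive", {
  g <- parse_smiles("c1ccccc1CCCC")$graph
  a <- mask_graph(g, 0.4, seed = 7)
  b <- mask_graph(g, 0.4, seed = 7)
  expect_identical(a$masked_nodes, b$masked_nodes)
  seeds_differ <- vapply(1:20, function(s)
    !identical(mask_graph(g, 0.4, seed = s)$masked_nodes, a$masked_nodes),
    TRUE)
  expect_true(any(seeds_differ))
})

test_that("mask realization replaces features and deletes interior bonds", {
  g <- parse_smiles("CCCCCCCCCC")$graph
  mg <- mask_graph(g, 0.3, seed = 2)
  enc <- apply_mask_for_encoding(mg)
  expect_identical(enc$n_atoms, g$n_atoms)
  expect_identical(sum(enc$atomic_number == 0L), 3L)
  # 9 path bonds - 2 interior = 7; boundary bonds to unmasked atoms kept
  expect_identical(nrow(enc$edges), 7L)
  # ratio-0 mask is the identity
  id <- apply_mask_for_encoding(mask_graph(g, 0, seed = 3))
  expect_identical(id$atomic_number, g$atomic_number)
  expect_identical(id$edges, g$edges)
  # full mask: every node carries the token, no surviving bonds
  full <- apply_mask_for_encoding(mask_graph(g, 1, seed = 3))
  expect_true(all(full$atomic_number == 0L))
  expect_identical(nrow(full$edges), 0L)
})

test_that("masking restarts on disconnected molecules until the quota is met", {
  # two disjoint fragments realized via a masked graph: build a graph with
  # two components directly
  g <- new_mol_graph(rep(6L, 6), rep(1L, 6), rep(FALSE, 6),
                     rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L)),
                     rep(1L, 4), rep(1L, 4))
  mg <- mask_graph(g, 1, seed = 4)
  expect_identical(length(mg$masked_nodes), 6L)
})
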