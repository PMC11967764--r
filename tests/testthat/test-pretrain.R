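# self-supervised objectives and the joint training loop

test_that("uniform logits give the closed-form cross-entropy sum(log K)", {
  cls <- init_structural_classifier(8L, c(100L, 1000L, 10000L), seed = 1)
  # zero weights and biases -> exactly uniform class probabilities
  for (i in seq_along(cls$heads)) {
    cls$heads[[i]]$W[] <- 0
    cls$heads[[i]]$b[] <- 0
  }
  lat <- matrix(rnorm(5 * 8), 5)
  labels <- cbind(sample(0:99, 5), sample(0:999, 5), sample(0:9999, 5))
  res <- mlct_loss(cls, lat, labels)
  expect_equal(res$loss, log(100) + log(1000) + log(10000), tolerance = 1e-8)
  expect_equal(res$per_head, log(c(100, 1000, 10000)), tolerance = 1e-8)
})

test_that("confident correct logits drive the loss to zero", {
  cls <- init_structural_classifier(2L, c(3L), seed = 1)
  cls$heads[[1]]$W[] <- 0
  cls$heads[[1]]$b <- c(50, 0, 0)   # point mass on class 0
  lat <- matrix(rnorm(4 * 2), 4)
  labels <- matrix(0L, 4, 1)
  expect_lt(mlct_loss(cls, lat, labels)$loss, 1e-6)
})

test_that("mean reduction makes N copies equal the single-sample loss", {
  cls <- init_structural_classifier(6L, c(4L, 7L), seed = 3)
  z <- matrix(rnorm(6), 1)
  lab <- matrix(c(2L, 5L), 1)
  single <- mlct_loss(cls, z, lab)$loss
  rep10 <- mlct_loss(cls, z[rep(1, 10), ], lab[rep(1, 10), ])$loss
  expect_equal(rep10, single, tolerance = 1e-10)
})

test_that("out-of-range pseudo-labels are rejected", {
  cls <- init_structural_classifier(4L, c(3L), seed = 1)
  expect_error(mlct_loss(cls, matrix(0, 1, 4), matrix(3L, 1, 1)),
               "out of range")
  expect_error(mlct_loss(cls, matrix(0, 0, 4), matrix(0L, 0, 1)), "empty")
})

test_that("contrastive loss is the mean Euclidean distance", {
  A <- matrix(rnorm(12), 3)
  expect_identical(mcl_loss(A, A)$loss, 0)
  B <- A; B[1, ] <- B[1, ] + c(1, 0, 0, 0)
  B[2, ] <- B[2, ] + c(1, 0, 0, 0); B[3, ] <- B[3, ] + c(1, 0, 0, 0)
  expect_equal(mcl_loss(A, B)$loss, 1)
  # hand-constructed distances 3 and 4 average to 3.5
  X <- rbind(c(0, 0), c(0, 0))
  Y <- rbind(c(3, 0), c(0, 4))
  expect_equal(mcl_loss(X, Y)$loss, 3.5)
  expect_equal(mcl_loss(X, Y, squared = TRUE)$loss, 12.5)
  expect_error(mcl_loss(X, Y[1, , drop = FALSE]), "mismatch")
})

test_that("total loss follows the training mode and rejects NaN", {
  expect_identical(total_loss(2, 3, "full"), 5)
  expect_identical(total_loss(2, 3, "mlct_only"), 2)
  expect_identical(total_loss(2, 3, "mcl_only"), 3)
  expect_identical(total_loss(0, 0, "full"), 0)
  expect_error(total_loss(NaN, 1, "full"), "non-finite")
  rep <- loss_report(1.5, 0.5, c(1, 0.5), "full")
  expect_equal(rep$l_all, 2)
})

test_that("analytic gradients match finite differences", {
  cfg <- encoder_config(n_layers = 2, hidden_dim = 5, graph_dim = 6,
                        latent_dim = 4, seed = 3)
  enc <- init_encoder(cfg)
  cls <- init_structural_classifier(4L, c(3L, 4L), seed = 2)
  g1 <- parse_smiles("c1ccncc1")$graph
  g2 <- parse_smiles("CC(O)C")$graph
  batch <- molssl:::build_graph_batch(list(g1, g2))
  mb <- molssl:::build_graph_batch(list(
    apply_mask_for_encoding(mask_graph(g1, 0.4, seed = 1)),
    apply_mask_for_encoding(mask_graph(g2, 0.4, seed = 2))))
  labels <- rbind(c(1L, 2L), c(0L, 3L))
  params <- c(enc$params, molssl:::.flatten_heads(cls))
  lossfun <- function(p) {
    e2 <- enc; e2$params <- p[names(enc$params)]
    c2 <- molssl:::.unflatten_heads(cls, p)
    f <- molssl:::encoder_forward(e2, batch)
    fm <- molssl:::encoder_forward(e2, mb)
    mlct_loss(c2, f$latent, labels)$loss + mcl_loss(f$latent, fm$latent)$loss
  }
  fwd <- molssl:::encoder_forward(enc, batch, keep_cache = TRUE)
  fwm <- molssl:::encoder_forward(enc, mb, keep_cache = TRUE)
  ml <- mlct_loss(cls, fwd$latent, labels, grad = TRUE)
  cl <- mcl_loss(fwd$latent, fwm$latent, grad = TRUE)
  grads <- molssl:::encoder_backward(enc, batch, fwd,
                                     ml$g_latent + cl$g_original)
  gm <- molssl:::encoder_backward(enc, mb, fwm, cl$g_masked)
  for (nm in names(gm)) grads[[nm]] <- grads[[nm]] + gm[[nm]]
  grads <- c(grads, molssl:::.flatten_heads_grads(ml$g_heads))
  eps <- 1e-5
  set.seed(77)
  for (nm in names(grads)) {
    for (j in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps; up <- lossfun(pp)
      pp[[nm]][j] <- pp[[nm]][j] - 2 * eps; dn <- lossfun(pp)
      expect_equal(grads[[nm]][j], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("the no-pretraining mode returns a fresh encoder and empty log", {
  co <- fixture_corpus()
  cfg <- pretrain_config(epochs = 5, granularities = c(4L),
                         encoder = fixture_encoder_config(seed = 9),
                         mode = "none", seed = 1)
  m <- mtss_pretrain(co, cfg)
  expect_identical(nrow(m$log), 0L)
  expect_identical(m$encoder$params,
                   init_encoder(fixture_encoder_config(seed = 9))$params)
  expect_identical(m$n_masked_batches, 0L)
})

test_that("training runs are reproducible and losses behave", {
  co <- fixture_two_family()
  cfg <- pretrain_config(epochs = 3, batch_size = 80,
                         granularities = c(2L, 4L),
                         encoder = fixture_encoder_config(seed = 2),
                         seed = 42)
  m1 <- mtss_pretrain(co, cfg)
  m2 <- mtss_pretrain(co, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$encoder$params, m2$encoder$params)
  # additivity and non-negativity at every logged epoch
  expect_equal(m1$log$l_all, m1$log$l_mlct + m1$log$l_mcl, tolerance = 1e-6)
  expect_true(all(m1$log$l_mlct >= 0))
  expect_true(all(m1$log$l_mcl >= 0))
})

test_that("ablation modes skip the branches they disable", {
  co <- fixture_two_family()
  base_enc <- fixture_encoder_config(seed = 2)
  m_mlct <- mtss_pretrain(co, pretrain_config(
    epochs = 2, batch_size = 80, granularities = c(2L),
    encoder = base_enc, mode = "mlct_only", seed = 1))
  expect_identical(m_mlct$n_masked_batches, 0L)   # masked branch never built
  expect_true(all(is.na(m_mlct$log$mcl_dist)))
  expect_identical(m_mlct$log$l_all, m_mlct$log$l_mlct)

  m_mcl <- mtss_pretrain(co, pretrain_config(
    epochs = 2, batch_size = 80, granularities = c(2L),
    encoder = base_enc, mode = "mcl_only", seed = 1))
  expect_gt(m_mcl$n_masked_batches, 0L)
  expect_identical(m_mcl$log$l_all, m_mcl$log$l_mcl)
  # no classifier gradient flows: heads remain at initialization
  init_cls <- init_structural_classifier(
    base_enc$latent_dim, c(2L), seed = derive_seed(1, "heads"))
  expect_identical(m_mcl$classifier$heads, init_cls$heads)
})

test_that("pretraining on a structured corpus learns its pseudo-labels", {
  m <- fixture_model()
  expect_lt(m$log$l_all[nrow(m$log)], m$log$l_all[1])
  expect_gt(m$log$acc_coarse[nrow(m$log)],
            3 / m$config$granularities[1])
  expect_lt(m$log$mcl_dist[nrow(m$log)], m$log$mcl_dist[1])
})

test_that("a corpus smaller than the largest granularity is rejected", {
  co <- fixture_two_family()
  expect_error(
    mtss_pretrain(co, pretrain_config(granularities = c(4L, 100000L),
                                      encoder = fixture_encoder_config())),
    "below the largest granularity")
})
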