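# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small 8-family corpus used across modules
fixture_corpus <- function() fixture("corpus", function()
  generate_corpus(synth_spec(n_molecules = 400, n_families = 8, seed = 101)))

# two-family corpus (aromatic benzene vs saturated cyclohexane)
fixture_two_family <- function() fixture("two_family", function()
  generate_corpus(synth_spec(n_molecules = 160, n_families = 2, seed = 202)))

# narrow encoder for fast training tests
fixture_encoder_config <- function(seed = 1)
  encoder_config(n_layers = 3, hidden_dim = 24, graph_dim = 32,
                 latent_dim = 16, seed = seed)

# a small pretrained model shared by analysis tests
fixture_model <- function() fixture("model", function() {
  co <- fixture_corpus()
  mtss_pretrain(co, pretrain_config(
    epochs = 20, batch_size = 128, granularities = c(4L, 8L),
    mask_ratio = 0.25, encoder = fixture_encoder_config(seed = 5),
    seed = 303))
})

# ---------------------------------------------------------------------------
# desk-scale study fixtures (built once, shared by the acceptance tests)

# pretraining corpus and model: n = 2000, granularities (4, 8, 16),
# mask ratio 0.25, 30 epochs; encoder keeps the 5-layer depth with
# desk-scale widths
fixture_desk_corpus <- function() fixture("desk_corpus", function()
  generate_corpus(synth_spec(n_molecules = 2000, n_families = 8,
                             seed = 424)))

fixture_desk_model <- function() fixture("desk_model", function()
  mtss_pretrain(fixture_desk_corpus(), pretrain_config(
    epochs = 30, batch_size = 256, granularities = c(4L, 8L, 16L),
    mask_ratio = 0.25,
    encoder = encoder_config(n_layers = 5, hidden_dim = 48, graph_dim = 64,
                             latent_dim = 32, seed = 7),
    seed = 505)))

# binary transfer task: aromatic-ring rule, n = 1000, cycloalkyl
# substituents for scaffold diversity
fixture_transfer_task <- function() fixture("transfer_task", function() {
  co <- generate_corpus(synth_spec(
    n_molecules = 1000, n_families = 12,
    substituents = default_substituents(rings = TRUE), seed = 626))
  co$labels <- generate_labels(co, "aromatic_ring")
  co
})

# two-family corpus for the latent-space analyses
fixture_analysis_corpus <- function() fixture("analysis_corpus", function()
  generate_corpus(synth_spec(n_molecules = 600, n_families = 2, seed = 727)))

# permute the nodes of a mol_graph with permutation p (new index of node i)
permute_graph <- function(g, p) {
  e <- cbind(p[g$edges[, 1]], p[g$edges[, 2]])
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2, 1), drop = FALSE]
  inv <- order(p)
  new_mol_graph(g$atomic_number[inv], g$chirality[inv], g$aromatic[inv],
                e, g$bond_type, g$bond_dir)
}

# degree multiset of a mol_graph
degree_multiset <- function(g) sort(vapply(g$adjacency, length, 0L))
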