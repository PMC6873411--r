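# Shared fixtures. Everything is generated in code; expensive objects are
# cached for the session.

.cache <- new.env(parent = emptyenv())

qm9 <- function() {
  if (is.null(.cache$qm9)) .cache$qm9 <- vocab_preset("qm9")
  .cache$qm9
}

# Small architecture used in unit tests (fast; the full-size defaults are
# exercised in the acceptance suite).
tiny_mpnn <- function() mpnn_config(n_message_layers = 2, message_hidden = 8,
                                    readout_dim = 10, head_hidden = 8)
tiny_dec <- function() decoder_config(n_layers = 2, hidden = 24, latent_dim = 6)

tiny_model <- function(seed = 11) {
  key <- paste0("model", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- init_model(qm9(), tiny_mpnn(), tiny_dec(), l = 2, seed = seed)
  .cache[[key]]
}

# A handful of featurized molecules.
test_graphs <- function() {
  if (is.null(.cache$graphs)) {
    smis <- c("CCO", "C=CC#N", "OC(=O)C", "C1CC1N", "FC(F)O")
    .cache$graphs <- lapply(smis, featurize, vocab = qm9())
  }
  .cache$graphs
}

fixture_smiles <- function(n = 60, seed = 5) {
  key <- sprintf("smi_%d_%d", n, seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- make_fixture_set(n, seed = seed)
  .cache[[key]]
}

small_dataset <- function(n = 60, seed = 5) {
  key <- sprintf("ds_%d_%d", n, seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- suppressWarnings(fixture_dataset(n, seed = seed))
  .cache[[key]]
}

# Two-carbon graphs with no hydrogens, used for the hand-computed
# count-profile examples.
bare_c2 <- function(order) {
  molecular_graph(data.frame(elem = c("C", "C"), charge = 0L, h = 0L),
                  data.frame(i = 1L, j = 2L, order = order), qm9())
}

# Model whose reward network outputs exactly 0.5 (all weights zero).
half_reward_model <- function() {
  m <- tiny_model()
  for (nm in grep("^rew\\.", names(m$params), value = TRUE))
    m$params[[nm]][] <- 0
  m
}

random_soft_graph <- function(model, scale = 3) {
  d <- model$dec_cfg$latent_dim
  decoder_forward(model, stats::rnorm(d, sd = scale), stats::rnorm(model$l))
}

expect_no_error <- function(expr) expect_error(expr, NA)
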