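# Network contracts: shapes, permutation invariance, reparameterization,
# and end-to-end gradient flow through the probabilistic graph.

test_that("all four networks are invariant to node permutation", {
  v <- qm9()
  cfg <- tiny_mpnn()
  params <- mpnn_init(v$p, cfg, out_dim = 4, seed = 7)
  model <- tiny_model()
  set.seed(30)
  smis <- fixture_smiles(40, seed = 13)
  for (smi in smis) {
    g <- featurize(smi, v)
    perm <- sample(g$n_heavy)
    gp <- permute_graph(g, perm)
    expect_equal(mpnn_forward(one_hot(g), cfg, 4, params),
                 mpnn_forward(one_hot(gp), cfg, 4, params), tolerance = 1e-5)
  }
  g <- featurize(smis[1], v); gp <- permute_graph(g, rev(seq_len(g$n_heavy)))
  y <- c(0.3, -0.7)
  expect_equal(encode(model, g, y), encode(model, gp, y), tolerance = 1e-5)
  expect_equal(reward_net_forward(model, one_hot(g)),
               reward_net_forward(model, one_hot(gp)), tolerance = 1e-5)
  expect_equal(predictor_forward(model, one_hot(g)),
               predictor_forward(model, one_hot(gp)), tolerance = 1e-5)
})

test_that("a graph with all-none edges passes no messages", {
  v <- qm9()
  cfg <- tiny_mpnn()
  params <- mpnn_init(v$p, cfg, out_dim = 3, seed = 9)
  g <- featurize("CCO", v)
  nobond <- molecular_graph(g$atoms,
                            data.frame(i = integer(0), j = integer(0),
                                       order = integer(0)), v)
  o1 <- mpnn_forward(one_hot(nobond), cfg, 3, params)
  # same nodes in a different order: output depends only on the node multiset
  o2 <- mpnn_forward(one_hot(permute_graph(nobond, c(3, 1, 2))), cfg, 3, params)
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("encoder output dimensions follow the latent configuration", {
  model <- tiny_model()
  enc <- encode(model, test_graphs()[[1]], c(0, 0))
  expect_length(enc$mu, 6L)
  expect_length(enc$sigma2, 6L)
  expect_true(all(enc$sigma2 > 0))
  # default architecture: d = 100
  vdef <- init_model(qm9(), seed = 2)
  encd <- encode(vdef, test_graphs()[[1]], c(0, 0))
  expect_length(encd$mu, 100L)
  expect_length(encd$sigma2, 100L)
})

test_that("reparameterization follows the variance-scaled form", {
  mu <- c(1, -2, 0.5); s2 <- c(0.3, 1.2, 2)
  expect_equal(reparameterize(mu, rep(0, 3)), mu)
  set.seed(5); z1 <- reparameterize(mu, s2)
  set.seed(5); z2 <- reparameterize(mu, s2)
  expect_equal(z1, z2)
  expect_equal(reparameterize(mu, s2, eps = c(1, 1, 1)), mu + s2)
  expect_equal(reparameterize(mu, s2, eps = c(1, 1, 1), use_sigma = TRUE),
               mu + sqrt(s2))
  # Monte-Carlo: mean of mu + eps*sigma2 is mu within 3 SE
  set.seed(6)
  draws <- replicate(10000, reparameterize(mu, s2))
  se <- s2 / sqrt(10000)
  expect_true(all(abs(rowMeans(draws) - mu) < 3 * se))
})

test_that("decoder raw output size equals m*p + m(m-1)q/2 and is a valid soft graph", {
  model <- tiny_model()
  expect_equal(model$n_raw, 14L * 12L + 91L * 4L)  # 532 for the QM9 preset
  expect_equal(ncol(model$params[["dec.out.W"]]), 532L)
  zmod <- init_model(vocab_preset("zinc"), tiny_mpnn(), tiny_dec(), seed = 3)
  expect_equal(zmod$n_raw, 4343L)
  set.seed(31)
  pg <- decoder_forward(model, rnorm(6), rnorm(2))
  expect_s3_class(pg, "probabilistic_graph")
  expect_no_error(probabilistic_graph(pg$node, pg$edge, model$vocab))
})

test_that("reward output is a probability; predictor output has length l", {
  model <- tiny_model()
  pg <- random_soft_graph(model)
  r <- reward_net_forward(model, pg)
  expect_gt(r, 0); expect_lt(r, 1)
  f <- predictor_forward(model, pg)
  expect_length(f, 2L)
  expect_true(all(is.finite(f)))
})

test_that("J1 gradients reach the decoder through the probabilistic graph", {
  model <- tiny_model()
  v <- qm9()
  graphs <- test_graphs()[1:3]
  Y <- matrix(rnorm(6), 3, 2)
  set.seed(33)
  d <- model$dec_cfg$latent_dim
  draws <- list(eps = matrix(rnorm(3 * d), 3, d),
                z_prior = matrix(rnorm(3 * d), 3, d),
                y_prior = matrix(rnorm(6), 3, 2))
  res <- j1_tape(model, graphs, Y, loss_weights(1, 1), draws)
  ad_backward(res$tp, res$loss)
  gr <- ad_grads(res$tp)
  for (nm in c("dec.out.W", "dec.l1.W", "enc.embed.W", "enc.mu.W"))
    expect_gt(sum(abs(gr[[nm]])), 0)
})

test_that("models round-trip through save/load with a manifest", {
  model <- tiny_model()
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_equal(m2$params, model$params)
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(manifest$m, 14L)
})
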