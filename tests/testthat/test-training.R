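# Property prior fitting, the joint training loop, gradient isolation and
# reproducibility.

test_that("property prior normalizes to mean 0 / sd 1 and recovers covariance", {
  set.seed(51)
  S <- matrix(c(4, 1.2, 1.2, 2), 2, 2)
  Y <- MASS::mvrnorm(4000, mu = c(120, 0.5), Sigma = S)
  colnames(Y) <- c("molwt", "logp")
  prior <- fit_property_prior(Y)
  expect_equal(unname(prior$mu), c(0, 0), tolerance = 1e-10)
  Yn <- normalize_properties(prior, Y)
  expect_equal(unname(colMeans(Yn)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Yn, 2, sd)), c(1, 1), tolerance = 1e-10)
  # prior covariance = correlation matrix of the raw properties
  expect_equal(prior$Sigma, stats::cov(Yn), tolerance = 1e-12)
  expect_equal(unname(denormalize_properties(prior, Yn)), unname(Y), tolerance = 1e-9)
})

test_that("a zero-variance property is rejected as degenerate", {
  Y <- cbind(molwt = rep(46.07, 10), logp = rnorm(10))
  expect_error(fit_property_prior(Y), class = "molgvae_degenerate_error")
})

test_that("training runs, logs every loss term, and is seed-reproducible", {
  ds <- small_dataset(40, seed = 6)
  cfg <- train_config(epochs = 2, batch_size = 10, seed = 3)
  fit1 <- train_model(ds, cfg, tiny_mpnn(), tiny_dec(), probe_n = 20)
  expect_equal(nrow(fit1$log), 2L)
  expect_true(all(c("recon", "kl", "rl_vae", "prop_vae", "rl_reward",
                    "prop_pred", "probe_validity") %in% names(fit1$log)))
  expect_true(all(is.finite(unlist(fit1$log))))
  fit2 <- train_model(ds, cfg, tiny_mpnn(), tiny_dec(), probe_n = 20)
  expect_equal(fit1$log, fit2$log)
  expect_equal(fit1$model$params, fit2$model$params)
})

test_that("beta1 = beta2 = 0 leaves the reward and predictor networks untouched", {
  ds <- small_dataset(40, seed = 6)
  cfg <- train_config(epochs = 1, batch_size = 10, seed = 3, beta1 = 0, beta2 = 0)
  model0 <- init_model(qm9(), tiny_mpnn(), tiny_dec(), seed = cfg$seed)
  fit <- train_model(ds, cfg, model = model0, probe_n = 0)
  for (nm in grep("^(rew|prd)\\.", names(model0$params), value = TRUE))
    expect_identical(fit$model$params[[nm]], model0$params[[nm]])
  for (nm in c("dec.out.W", "enc.mu.W"))
    expect_false(identical(fit$model$params[[nm]], model0$params[[nm]]))
})

test_that("gradients are isolated: J2 never reaches the VAE parameters", {
  model <- tiny_model()
  graphs <- test_graphs()[1:3]
  Y <- matrix(rnorm(6), 3, 2)
  d <- model$dec_cfg$latent_dim
  set.seed(52)
  draws <- list(eps = matrix(rnorm(3 * d), 3, d),
                z_prior = matrix(rnorm(3 * d), 3, d),
                y_prior = matrix(rnorm(6), 3, 2))
  fw <- vae_forward_values(model, graphs, Y, draws)
  j2 <- j2_tape(model, graphs, Y, loss_weights(1, 1), fw$soft_vals,
                fw$R_recon, fw$R_prior)
  ad_backward(j2$tp, j2$loss)
  gr <- ad_grads(j2$tp)
  for (nm in grep("^(enc|dec)\\.", names(model$params), value = TRUE))
    expect_equal(sum(abs(gr[[nm]])), 0)
  for (nm in c("rew.out.W", "prd.out.W"))
    expect_gt(sum(abs(gr[[nm]])), 0)
})

test_that("training can resume from an existing model", {
  ds <- small_dataset(40, seed = 6)
  cfg <- train_config(epochs = 1, batch_size = 10, seed = 3)
  fit1 <- train_model(ds, cfg, tiny_mpnn(), tiny_dec(), probe_n = 0)
  fit2 <- train_model(ds, cfg, model = fit1$model, probe_n = 0)
  expect_false(identical(fit1$model$params[["dec.out.W"]],
                         fit2$model$params[["dec.out.W"]]))
  # normalization statistics travel with the model
  expect_equal(fit2$model$prior$center, fit1$model$prior$center)
})

test_that("the epoch hook observes every epoch", {
  ds <- small_dataset(40, seed = 6)
  seen <- integer(0)
  train_model(ds, train_config(epochs = 2, batch_size = 20, seed = 4),
              tiny_mpnn(), tiny_dec(), probe_n = 0,
              epoch_hook = function(epoch, model) seen <<- c(seen, epoch))
  expect_equal(seen, 1:2)
})
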