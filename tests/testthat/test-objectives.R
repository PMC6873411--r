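# Count profiles, the approximate graph-matching loss, KL, RL and property
# losses, and the combined objectives.

test_that("count profile of ethane matches hand enumeration (ordered pairs)", {
  pr <- count_profile(bare_c2(1))
  expect_equal(unname(pr$atom_counts["C"]), 2)
  expect_equal(unname(pr$bond_counts), c(2, 0, 0))  # both directions counted
  expect_equal(unname(pr$atom_bond_counts["single", "C"]), 2)
  expect_equal(pr$atom_bond_atom_counts[1, 1, 1], 2)
  expect_equal(sum(pr$atom_bond_atom_counts[2:3, , ]), 0)
})

test_that("profiles are permutation-invariant, zero on empty graphs, integral on one-hot", {
  v <- qm9()
  empty <- molecular_graph(data.frame(elem = character(0), charge = integer(0),
                                      h = integer(0)),
                           data.frame(i = integer(0), j = integer(0),
                                      order = integer(0)), v)
  pe <- count_profile(empty)
  expect_true(all(unlist(pe[1:2]) == 0) && all(pe$atom_bond_counts == 0))
  set.seed(41)
  for (g in test_graphs()) {
    p0 <- count_profile(g)
    expect_true(all(unlist(lapply(p0, function(x) x == round(x)))))
    pp <- count_profile(permute_graph(g, sample(g$n_heavy)))
    expect_equal(p0, pp)
  }
})

test_that("approximate reconstruction loss matches the worked example and invariances", {
  expect_equal(approx_recon_loss(bare_c2(1), one_hot(bare_c2(2))), 24)
  set.seed(42)
  for (g in test_graphs()) {
    expect_equal(approx_recon_loss(g, one_hot(g)), 0)
    expect_equal(approx_recon_loss(g, one_hot(permute_graph(g, sample(g$n_heavy)))), 0)
  }
  # non-negative and differentiable-side consistent on soft graphs
  model <- tiny_model()
  set.seed(43)
  for (k in 1:5) {
    pg <- random_soft_graph(model)
    expect_gte(approx_recon_loss(test_graphs()[[1]], pg), 0)
  }
})

test_that("profile terms on the tape equal the plain implementation", {
  model <- tiny_model()
  v <- qm9()
  graphs <- test_graphs()[1:3]
  tp <- ad_tape()
  st <- stack_graphs(lapply(graphs, one_hot), v, model$pairs)
  pgb <- list(node = ad_const(tp, st$node), edge = ad_const(tp, st$edge),
              B = 3L, m = v$max_nodes, np = v$n_pairs)
  prof <- ad_profile_nodes(tp, pgb, v, edge_indices(3L, v$max_nodes, model$pairs))
  plain <- lapply(graphs, count_profile)
  for (g in 1:3) {
    expect_equal(unname(prof$atomc$value[g, ]), unname(plain[[g]]$atom_counts))
    expect_equal(unname(prof$bondc$value[g, ]), unname(plain[[g]]$bond_counts))
    for (b in 1:3) {
      expect_equal(unname(prof$ab[[b]]$value[g, ]),
                   unname(plain[[g]]$atom_bond_counts[b, ]))
      expect_equal(unname(prof$aba[[b]]$value[g, ]),
                   as.vector(plain[[g]]$atom_bond_atom_counts[b, , ]))
    }
  }
})

test_that("KL loss matches the closed form and a Monte-Carlo estimate", {
  expect_equal(kl_loss(0, 1), 0)
  expect_equal(kl_loss(1, 1), 0.5)
  expect_error(kl_loss(0, -1), class = "molgvae_domain_error")
  set.seed(44)
  for (k in 1:20) {
    mu <- rnorm(5); s2 <- exp(rnorm(5))
    expect_gte(kl_loss(mu, s2), 0)
  }
  # MC: E_q[log q(z) - log p(z)] over 1e5 draws, within 3 standard errors
  mu <- 0.7; s2 <- 0.6
  n <- 1e5
  set.seed(45)
  z <- rnorm(n, mu, sqrt(s2))
  samp <- dnorm(z, mu, sqrt(s2), log = TRUE) - dnorm(z, log = TRUE)
  expect_lt(abs(mean(samp) - kl_loss(mu, s2)), 3 * sd(samp) / sqrt(n))
})

test_that("RL losses reproduce the analytic reference values", {
  model <- half_reward_model()  # r(.) = 0.5 exactly
  pg1 <- random_soft_graph(model)
  pg2 <- random_soft_graph(model)
  expect_equal(rl_loss_vae(model, pg1, pg2), 2 * log(2), tolerance = 1e-12)
  g <- test_graphs()[[1]]
  expect_equal(rl_loss_reward_net(model, g, pg1, pg2), 3 * log(2), tolerance = 1e-12)
  # near-perfect reward -> loss collapses toward the clamp floor
  good <- model
  good$params[["rew.out.b"]][] <- 30
  expect_lt(rl_loss_vae(good, pg1, pg2), 1e-6)
  # confident wrong prediction on a valid data graph hits the clamp ceiling
  bad <- model
  bad$params[["rew.out.b"]][] <- -30
  expect_gt(rl_loss_reward_net(bad, g, pg1, pg2), -log(1e-7) * 0.9)
})

test_that("property losses are gated by the external reward", {
  model <- tiny_model()
  v <- qm9()
  # a soft graph that decodes to the empty (invalid) graph
  m <- v$max_nodes
  node <- matrix(0, m, v$p)
  node[, v$atom_cols[v$none_atom]] <- 1
  node[, v$charge_cols[v$charge0]] <- 1
  node[, v$h_cols[v$h0]] <- 1
  edge <- array(0, dim = c(m, m, 4)); edge[, , v$none_bond] <- 1
  pg_none <- probabilistic_graph(node, edge, v)
  expect_equal(property_loss_vae(model, c(0, 0), pg_none, pg_none, c(0, 0)), 0)
  # valid reconstruction contributes its squared residual
  gv <- one_hot(test_graphs()[[1]])
  f <- predictor_forward(model, gv)
  loss <- property_loss_vae(model, f + c(1, 0), gv, pg_none, c(0, 0))
  expect_equal(loss, 1, tolerance = 1e-10)
  # predictor loss: pure squared error
  g <- test_graphs()[[2]]
  fg <- predictor_forward(model, one_hot(g))
  expect_equal(property_loss_predictor(model, fg, g), 0, tolerance = 1e-12)
  expect_equal(property_loss_predictor(model, fg + c(3, 4), g), 25, tolerance = 1e-8)
})

test_that("J1 reduces to the plain VAE objective under the ablation weights", {
  model <- tiny_model()
  graphs <- test_graphs()[1:3]
  Y <- matrix(rnorm(6), 3, 2)
  d <- model$dec_cfg$latent_dim
  set.seed(46)
  draws <- list(eps = matrix(rnorm(3 * d), 3, d),
                z_prior = matrix(rnorm(3 * d), 3, d),
                y_prior = matrix(rnorm(6), 3, 2))
  full <- objective_j1(model, graphs, Y, loss_weights(1, 1), draws = draws)
  a1 <- objective_j1(model, graphs, Y, loss_weights(0, 0), draws = draws)
  expect_equal(a1$value, unname(a1$parts["recon"] + a1$parts["kl"]))
  expect_equal(a1$parts[c("recon", "kl")], full$parts[c("recon", "kl")])
  a2 <- objective_j1(model, graphs, Y, loss_weights(1, 0), draws = draws)
  expect_equal(a2$value,
               unname(a2$parts["recon"] + a2$parts["kl"] + a2$parts["rl_vae"]))
  j2_0 <- objective_j2(model, graphs, Y, loss_weights(0, 0), draws = draws)
  expect_equal(j2_0$value, 0)
})

test_that("fast batched decoding agrees with graph-by-graph decode + reward", {
  model <- tiny_model()
  v <- qm9()
  set.seed(47)
  B <- 40
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  d <- model$dec_cfg$latent_dim
  pgb <- nn_decoder(tp, pn, ad_const(tp, matrix(rnorm(B * d) * 3, B, d)),
                    ad_const(tp, matrix(rnorm(B * 2), B, 2)), model)
  fast <- decode_validity_pgb(pgb, v, model$pairs)
  slow <- vapply(seq_len(B), function(g)
    validity_reward(decode_graph(pg_from_batch(pgb, g, v, model$pairs))),
    numeric(1))
  expect_equal(fast, slow)
})
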