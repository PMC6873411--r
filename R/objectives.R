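# Learning objectives. The reconstruction loss replaces exact (O(m^4)) graph
# matching with squared distances between four permutation-invariant count
# profiles: atom types, bond types, atom-bond pairs, and atom-bond-atom
# triples. Sums over node pairs run over ordered pairs i != j (each undirected
# bond counted twice), a convention fixed project-wide. The "none" atom column
# and "none" bond channel are discarded before counting; charge and
# explicit-H contributions are weighted by each node's non-"none" probability
# so padding carries no counts.

#' Loss weights
#' @param beta1 Weight of the reinforcement-learning losses (default 1).
#' @param beta2 Weight of the property-prediction losses (default 1).
#' @export
loss_weights <- function(beta1 = 1, beta2 = 1) {
  if (beta1 < 0 || beta2 < 0) abort_domain("loss weights must be non-negative")
  list(beta1 = beta1, beta2 = beta2)
}

LOG_CLAMP <- 1e-7

#' Permutation-invariant count profile of a (probabilistic) graph
#'
#' @param pg A `probabilistic_graph` or [molecular_graph()].
#' @return An object of class `count_profile`: `atom_counts` (atom types
#'   excluding `"none"`, then charges, then explicit-H counts), `bond_counts`
#'   (single/double/triple over ordered pairs), `atom_bond_counts` (3 x A) and
#'   `atom_bond_atom_counts` (3 x A x A), A = number of real atom types.
#' @export
count_profile <- function(pg) {
  if (inherits(pg, "molecular_graph")) pg <- one_hot(pg)
  stopifnot(inherits(pg, "probabilistic_graph"))
  vocab <- pg$vocab
  m <- vocab$max_nodes
  atom_real <- setdiff(vocab$atom_cols, vocab$atom_cols[vocab$none_atom])
  A <- length(atom_real)
  w <- 1 - pg$node[, vocab$atom_cols[vocab$none_atom]]
  V <- pg$node[, atom_real, drop = FALSE]
  CH <- pg$node[, c(vocab$charge_cols, vocab$h_cols), drop = FALSE] * w
  atom_counts <- c(colSums(V), colSums(CH))
  names(atom_counts) <- c(vocab$atom_types[-vocab$none_atom],
                          paste0("charge", vocab$formal_charges),
                          paste0("h", vocab$explicit_h_counts))
  ch_real <- match(c("single", "double", "triple"), vocab$bond_types)
  bond_counts <- numeric(3)
  ab <- matrix(0, 3, A, dimnames = list(c("single", "double", "triple"),
                                        vocab$atom_types[-vocab$none_atom]))
  aba <- array(0, dim = c(3, A, A))
  for (b in 1:3) {
    E <- pg$edge[, , ch_real[b]]
    diag(E) <- 0
    bond_counts[b] <- sum(E)           # ordered pairs: symmetric sum counts both
    ab[b, ] <- colSums(V * rowSums(E))
    aba[b, , ] <- crossprod(V, E %*% V)
  }
  names(bond_counts) <- c("single", "double", "triple")
  structure(list(atom_counts = atom_counts, bond_counts = bond_counts,
                 atom_bond_counts = ab, atom_bond_atom_counts = aba),
            class = "count_profile")
}

#' Approximate graph-matching reconstruction loss
#'
#' Sum of squared Euclidean distances between the four count-profile
#' components of a reference graph and a probabilistic reconstruction;
#' invariant to node permutation of either argument, differentiable in the
#' probabilistic graph, and zero whenever the two profiles coincide (distinct
#' non-isomorphic graphs can share a profile -- the approximation's known
#' collision mode).
#'
#' @param g Reference [molecular_graph()] (or `probabilistic_graph`).
#' @param pg A `probabilistic_graph` over the same vocabulary.
#' @return Non-negative scalar.
#' @export
approx_recon_loss <- function(g, pg) {
  vg <- if (inherits(g, "molecular_graph")) g$vocab else g$vocab
  if (!same_vocab(vg, pg$vocab)) abort_shape("graphs use different vocabularies")
  a <- count_profile(g)
  b <- count_profile(pg)
  sum((a$atom_counts - b$atom_counts)^2) +
    sum((a$bond_counts - b$bond_counts)^2) +
    sum((a$atom_bond_counts - b$atom_bond_counts)^2) +
    sum((a$atom_bond_atom_counts - b$atom_bond_atom_counts)^2)
}

#' Kullback-Leibler regularization of the latent posterior
#'
#' Closed form between a diagonal Gaussian and the standard normal prior:
#' `0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))`.
#'
#' @param mu,sigma2 Numeric vectors of equal length; `sigma2 > 0`.
#' @return Non-negative scalar.
#' @export
kl_loss <- function(mu, sigma2) {
  check_shape(length(mu) == length(sigma2), "mu and sigma2 must have equal length")
  if (any(sigma2 <= 0)) abort_domain("variances must be strictly positive")
  0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))
}

clamp01 <- function(x) pmin(pmax(x, LOG_CLAMP), 1 - LOG_CLAMP)

#' Reinforcement-learning loss for the VAE (policy side)
#'
#' `-log r(recon_pg) - log r(prior_pg)`: the decoder is pushed toward
#' probabilistic graphs the reward network scores as valid. Reward-network
#' outputs are clamped away from 0/1 by 1e-7 before the log.
#'
#' @param model A `molgvae_model`.
#' @param recon_pg Decoder output from the posterior latent.
#' @param prior_pg Decoder output from prior draws of (z, y).
#' @return Scalar loss.
#' @export
rl_loss_vae <- function(model, recon_pg, prior_pg) {
  r1 <- reward_net_forward(model, recon_pg)
  r2 <- reward_net_forward(model, prior_pg)
  -log(clamp01(r1)) - log(clamp01(r2))
}

bce <- function(label, r) {
  r <- clamp01(r)
  -label * log(r) - (1 - label) * log(1 - r)
}

#' Reinforcement-learning loss for the reward network
#'
#' Three binary cross-entropy terms: the data graph (label
#' `validity_reward(g_data)`, 1 for training data), and the argmax-decoded
#' reconstruction and prior sample (labels from the external reward on the
#' decoded graphs).
#'
#' @param model A `molgvae_model`.
#' @param g_data Training [molecular_graph()].
#' @param recon_pg,prior_pg Decoder outputs (probabilistic graphs).
#' @return Scalar loss.
#' @export
rl_loss_reward_net <- function(model, g_data, recon_pg, prior_pg) {
  bce(validity_reward(g_data), reward_net_forward(model, g_data)) +
    bce(validity_reward(decode_graph(recon_pg)), reward_net_forward(model, recon_pg)) +
    bce(validity_reward(decode_graph(prior_pg)), reward_net_forward(model, prior_pg))
}

#' Auxiliary property loss for the VAE
#'
#' `R(decode(recon_pg)) * ||y - f(recon_pg)||^2 +`
#' `R(decode(prior_pg)) * ||y_prior - f(prior_pg)||^2`: only probabilistic
#' graphs whose argmax decoding is chemically valid contribute.
#'
#' @param model A `molgvae_model`.
#' @param y Normalized property vector of the data graph.
#' @param recon_pg,prior_pg Decoder outputs.
#' @param y_prior The property vector drawn from the prior for `prior_pg`.
#' @return Non-negative scalar.
#' @export
property_loss_vae <- function(model, y, recon_pg, prior_pg, y_prior) {
  R1 <- validity_reward(decode_graph(recon_pg))
  R2 <- validity_reward(decode_graph(prior_pg))
  v1 <- if (R1 > 0) sum((y - predictor_forward(model, recon_pg))^2) else 0
  v2 <- if (R2 > 0) sum((y_prior - predictor_forward(model, prior_pg))^2) else 0
  R1 * v1 + R2 * v2
}

#' Auxiliary property loss for the predictor network
#'
#' Squared error between the data property vector and the predictor's output
#' on the data graph.
#'
#' @param model A `molgvae_model`.
#' @param y Normalized property vector.
#' @param g Data [molecular_graph()].
#' @return Non-negative scalar.
#' @export
property_loss_predictor <- function(model, y, g) {
  sum((y - predictor_forward(model, g))^2)
}

# ---- batched tape construction (training path) -----------------------------

# Stack plain count profiles of data graphs into constant matrices matching
# the tape-side layout (per-bond-type blocks; atom-bond-atom flattened
# column-major).
profile_consts <- function(graphs, vocab) {
  B <- length(graphs)
  profs <- lapply(graphs, count_profile)
  atomc <- do.call(rbind, lapply(profs, function(p) p$atom_counts))
  bondc <- do.call(rbind, lapply(profs, function(p) p$bond_counts))
  ab <- lapply(1:3, function(b)
    do.call(rbind, lapply(profs, function(p) p$atom_bond_counts[b, , drop = TRUE])))
  aba <- lapply(1:3, function(b)
    do.call(rbind, lapply(profs, function(p) as.vector(p$atom_bond_atom_counts[b, , ]))))
  list(atomc = atomc, bondc = bondc, ab = ab, aba = aba)
}

# Tape-side count-profile nodes for a decoded probabilistic-graph batch.
ad_profile_nodes <- function(tp, pgb, vocab, idx) {
  B <- pgb$B; m <- pgb$m
  atom_real <- setdiff(vocab$atom_cols, vocab$atom_cols[vocab$none_atom])
  ch_real <- match(c("single", "double", "triple"), vocab$bond_types)
  ones_col <- ad_const(tp, matrix(1, B * m, 1))
  wnone <- ad_slice_cols(pgb$node, vocab$atom_cols[vocab$none_atom], tp)
  w <- ad_sub(ad_const(tp, matrix(1, B * m, 1)), wnone, tp)
  V <- ad_slice_cols(pgb$node, atom_real, tp)
  CH <- ad_mul_colvec(ad_slice_cols(pgb$node, c(vocab$charge_cols, vocab$h_cols), tp), w, tp)
  atomc <- ad_pool_sum(ad_concat_cols(list(V, CH), tp), B, m, tp)
  bondc <- ad_scale(ad_pool_sum(ad_slice_cols(pgb$edge, ch_real, tp), B, pgb$np, tp), 2, tp)
  ab <- vector("list", 3)
  aba <- vector("list", 3)
  for (b in 1:3) {
    deg <- ad_edge_message(ones_col, pgb$edge, ch_real[b], idx, tp)
    ab[[b]] <- ad_pool_sum(ad_mul_colvec(V, deg, tp), B, m, tp)
    aba[[b]] <- ad_pool_outer(V, ad_edge_message(V, pgb$edge, ch_real[b], idx, tp),
                              B, m, tp)
  }
  list(atomc = atomc, bondc = bondc, ab = ab, aba = aba)
}

ad_sq_diff_sum <- function(tp, node, const_mat, rows = NULL) {
  if (!is.null(rows)) node <- ad_slice_rows(node, rows, tp)
  d <- ad_sub(node, ad_const(tp, const_mat), tp)
  ad_sum(ad_mul(d, d, tp), tp)
}

# Reconstruction-loss node: sum over the data examples (an optional row
# subset of the decoded batch) of the four profile distances.
ad_recon_loss <- function(tp, pgb, consts, vocab, idx, rows = NULL) {
  prof <- ad_profile_nodes(tp, pgb, vocab, idx)
  loss <- ad_add(ad_sq_diff_sum(tp, prof$atomc, consts$atomc, rows),
                 ad_sq_diff_sum(tp, prof$bondc, consts$bondc, rows), tp)
  for (b in 1:3) {
    loss <- ad_add(loss, ad_sq_diff_sum(tp, prof$ab[[b]], consts$ab[[b]], rows), tp)
    loss <- ad_add(loss, ad_sq_diff_sum(tp, prof$aba[[b]], consts$aba[[b]], rows), tp)
  }
  loss
}

ad_kl_loss <- function(tp, mu, sigma2) {
  ones <- ad_const(tp, matrix(1, nrow(mu$value), ncol(mu$value)))
  inner <- ad_sub(ad_sub(ad_add(ad_mul(mu, mu, tp), sigma2, tp), ones, tp),
                  ad_log(sigma2, tp), tp)
  ad_scale(ad_sum(inner, tp), 0.5, tp)
}

# -sum(log(clamp(r))) for a B x 1 reward-output node.
ad_neg_log <- function(tp, r) {
  ad_scale(ad_sum(ad_log(ad_clamp(r, LOG_CLAMP, 1 - LOG_CLAMP, tp), tp), tp), -1, tp)
}

# Binary cross-entropy of a B x 1 reward output against 0/1 labels.
ad_bce <- function(tp, r, labels) {
  B <- nrow(r$value)
  rc <- ad_clamp(r, LOG_CLAMP, 1 - LOG_CLAMP, tp)
  L <- ad_const(tp, matrix(labels, B, 1))
  Lc <- ad_const(tp, matrix(1 - labels, B, 1))
  ones <- ad_const(tp, matrix(1, B, 1))
  t1 <- ad_mul(L, ad_log(rc, tp), tp)
  t2 <- ad_mul(Lc, ad_log(ad_sub(ones, rc, tp), tp), tp)
  ad_scale(ad_sum(ad_add(t1, t2, tp), tp), -1, tp)
}

# Row-gated squared error: sum_g w_g * ||Y_g - f_g||^2.
ad_gated_sq <- function(tp, fnode, Y, gate) {
  d <- ad_sub(fnode, ad_const(tp, Y), tp)
  sq <- ad_mul(d, d, tp)
  ad_sum(ad_mul_colvec(sq, ad_const(tp, matrix(gate, ncol = 1)), tp), tp)
}

# Vectorized external reward over a stacked batch of probabilistic graphs:
# argmax-decode every example and apply the sanitization rule, without
# materializing molecular_graph objects. Agrees exactly with
# validity_reward(decode_graph(.)) (asserted in the test suite).
decode_validity <- function(node_vals, edge_vals, B, vocab, pairs) {
  m <- vocab$max_nodes; np <- nrow(pairs)
  a_idx <- max.col(node_vals[, vocab$atom_cols, drop = FALSE], ties.method = "first")
  c_idx <- max.col(node_vals[, vocab$charge_cols, drop = FALSE], ties.method = "first")
  h_idx <- max.col(node_vals[, vocab$h_cols, drop = FALSE], ties.method = "first")
  keep <- a_idx != vocab$none_atom
  ev <- as.numeric(vocab$explicit_h_counts[h_idx])
  ch <- max.col(edge_vals, ties.method = "first")
  orders <- match(vocab$bond_types, c("single", "double", "triple"))[ch]
  off <- rep((seq_len(B) - 1L) * m, each = np)
  i_g <- rep(pairs[, 1], B) + off
  j_g <- rep(pairs[, 2], B) + off
  active <- !is.na(orders) & keep[i_g] & keep[j_g]
  if (any(active)) {
    s <- rowsum(c(orders[active], orders[active]), c(i_g[active], j_g[active]))
    at <- as.integer(rownames(s))
    ev[at] <- ev[at] + s[, 1]
  }
  maxv <- vocab$max_valence[cbind(a_idx, c_idx)]
  bad <- keep & (is.na(maxv) | ev > maxv)
  keep_any <- colSums(matrix(keep, m, B)) > 0
  bad_any <- colSums(matrix(bad, m, B)) > 0
  as.numeric(keep_any & !bad_any)
}

decode_validity_pgb <- function(pgb, vocab, pairs) {
  decode_validity(pgb$node$value, pgb$edge$value, pgb$B, vocab, pairs)
}

# Build the J1 tape for one batch. draws: list(eps B x d, z_prior B x d,
# y_prior B x l). The reconstruction pass (posterior z) and the prior pass
# share one decoder/reward/predictor evaluation over a 2B-row merged batch;
# rows 1..B are the reconstructions, rows B+1..2B the prior samples. Returns
# the loss node, per-term values, decoded external rewards and the decoder
# output values (reused as constants by the J2 tape).
j1_tape <- function(model, graphs, Y, weights, draws, use_sigma = FALSE) {
  vocab <- model$vocab; pairs <- model$pairs
  B <- length(graphs)
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  data_stack <- stack_graphs(lapply(graphs, one_hot), vocab, pairs)
  batch <- batch_const(tp, data_stack, pairs)
  ynode <- ad_const(tp, Y)
  enc <- nn_encoder(tp, pn, batch, ynode, model)
  epsn <- ad_const(tp, draws$eps)
  scale_n <- if (use_sigma) {
    ad_exp(ad_scale(ad_log(enc$sigma2, tp), 0.5, tp), tp)
  } else enc$sigma2
  z <- ad_add(enc$mu, ad_mul(epsn, scale_n, tp), tp)
  z_all <- ad_concat_rows(list(z, ad_const(tp, draws$z_prior)), tp)
  y_all <- ad_concat_rows(list(ynode, ad_const(tp, draws$y_prior)), tp)
  pgb <- nn_decoder(tp, pn, z_all, y_all, model)
  soft_batch <- list(node = pgb$node, edge = pgb$edge, B = 2L * B,
                     m = vocab$max_nodes, np = vocab$n_pairs,
                     idx = edge_indices(2L * B, vocab$max_nodes, pairs))
  consts <- profile_consts(graphs, vocab)
  recon <- ad_recon_loss(tp, pgb, consts, vocab, soft_batch$idx, rows = seq_len(B))
  kl <- ad_kl_loss(tp, enc$mu, enc$sigma2)
  rl <- ad_neg_log(tp, nn_reward(tp, pn, soft_batch, model))
  Rv <- decode_validity_pgb(pgb, vocab, pairs)
  R_recon <- Rv[seq_len(B)]; R_prior <- Rv[B + seq_len(B)]
  prop <- ad_gated_sq(tp, nn_predictor(tp, pn, soft_batch, model),
                      rbind(Y, draws$y_prior), Rv)
  loss <- ad_add(ad_add(recon, kl, tp),
                 ad_add(ad_scale(rl, weights$beta1, tp),
                        ad_scale(prop, weights$beta2, tp), tp), tp)
  list(tp = tp, loss = loss,
       parts = c(recon = as.numeric(recon$value), kl = as.numeric(kl$value),
                 rl_vae = as.numeric(rl$value), prop_vae = as.numeric(prop$value)),
       R_recon = R_recon, R_prior = R_prior,
       soft_vals = list(node = pgb$node$value, edge = pgb$edge$value))
}

# Build the J2 tape: reward-network BCE on the data graphs and on the two
# (constant) decoder outputs -- one merged 3B-row reward pass -- plus the
# predictor loss on the data graphs.
j2_tape <- function(model, graphs, Y, weights, soft_vals, R_recon, R_prior) {
  vocab <- model$vocab; pairs <- model$pairs
  B <- length(graphs)
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  data_stack <- stack_graphs(lapply(graphs, one_hot), vocab, pairs)
  data_batch <- batch_const(tp, data_stack, pairs)
  all_batch <- list(node = ad_const(tp, rbind(data_stack$node, soft_vals$node)),
                    edge = ad_const(tp, rbind(data_stack$edge, soft_vals$edge)),
                    B = 3L * B, m = vocab$max_nodes, np = vocab$n_pairs,
                    idx = edge_indices(3L * B, vocab$max_nodes, pairs))
  R_data <- vapply(graphs, validity_reward, numeric(1))
  rl <- ad_bce(tp, nn_reward(tp, pn, all_batch, model), c(R_data, R_recon, R_prior))
  prop <- ad_gated_sq(tp, nn_predictor(tp, pn, data_batch, model), Y, rep(1, B))
  loss <- ad_add(ad_scale(rl, weights$beta1, tp), ad_scale(prop, weights$beta2, tp), tp)
  list(tp = tp, loss = loss,
       parts = c(rl_reward = as.numeric(rl$value), prop_pred = as.numeric(prop$value)))
}

make_draws <- function(model, B, prior) {
  d <- model$dec_cfg$latent_dim
  list(eps = matrix(stats::rnorm(B * d), B, d),
       z_prior = matrix(stats::rnorm(B * d), B, d),
       y_prior = sample_y_unconditional(prior, B))
}

#' Combined VAE objective J1 over a batch
#'
#' Sums, over the batch, the approximate reconstruction loss plus KL, plus
#' `beta1` times the policy-side RL loss and `beta2` times the gated property
#' loss. Its gradient touches only the encoder/decoder parameters.
#'
#' @param model A `molgvae_model` (with a fitted property prior, or pass
#'   `prior`).
#' @param graphs List of [molecular_graph()] training graphs.
#' @param y B x l matrix of normalized property vectors.
#' @param weights A [loss_weights()].
#' @param draws Optional list with `eps`, `z_prior` (B x d) and `y_prior`
#'   (B x l); drawn from the current RNG when omitted.
#' @param prior A `property_prior` (defaults to `model$prior`).
#' @return List with `value` and the per-term breakdown `parts`.
#' @export
objective_j1 <- function(model, graphs, y, weights = loss_weights(), draws = NULL,
                         prior = model$prior) {
  y <- matrix(y, nrow = length(graphs))
  if (is.null(draws)) {
    if (is.null(prior)) abort_domain("a property prior is required to draw y_prior")
    draws <- make_draws(model, length(graphs), prior)
  }
  res <- j1_tape(model, graphs, y, weights, draws)
  list(value = as.numeric(res$loss$value), parts = res$parts)
}

#' Combined auxiliary objective J2 over a batch
#'
#' `beta1` times the reward-network BCE (data graph, reconstruction, prior
#' sample) plus `beta2` times the predictor loss on the data graphs. Its
#' gradient touches only the reward and predictor networks.
#'
#' @inheritParams objective_j1
#' @return List with `value` and `parts`.
#' @export
objective_j2 <- function(model, graphs, y, weights = loss_weights(), draws = NULL,
                         prior = model$prior) {
  y <- matrix(y, nrow = length(graphs))
  if (is.null(draws)) {
    if (is.null(prior)) abort_domain("a property prior is required to draw y_prior")
    draws <- make_draws(model, length(graphs), prior)
  }
  j1 <- j1_tape(model, graphs, y, weights, draws)
  j2 <- j2_tape(model, graphs, y, weights, j1$soft_vals, j1$R_recon, j1$R_prior)
  list(value = as.numeric(j2$loss$value), parts = j2$parts)
}
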