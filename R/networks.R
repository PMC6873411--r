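# The four networks: MPNN encoder q_phi, fully-connected decoder p_theta,
# MPNN reward network r, MPNN property predictor f. Message passing follows
# the gated style: messages are per-bond-type linear transforms of neighbor
# states, convex-combined by the (soft) edge-type probabilities excluding
# "none" -- so "none" edges carry no message and one-hot and soft graphs share
# one code path -- followed by a GRU-style state update. The readout sums a
# per-node aggregation layer, making every network invariant to node
# permutation.

#' MPNN configuration
#'
#' Defaults follow the study architecture: three message passing layers with
#' 50 hidden units, a 100-dimensional node aggregation layer, then two
#' fully-connected layers with 100 tanh hidden units.
#' @param n_message_layers,message_hidden,readout_dim,head_hidden Positive integers.
#' @param head_activation Activation of the head layers (`"tanh"`).
#' @export
mpnn_config <- function(n_message_layers = 3L, message_hidden = 50L,
                        readout_dim = 100L, head_hidden = 100L,
                        head_activation = "tanh") {
  cfg <- list(n_message_layers = as.integer(n_message_layers),
              message_hidden = as.integer(message_hidden),
              readout_dim = as.integer(readout_dim),
              head_hidden = as.integer(head_hidden),
              head_activation = head_activation)
  if (any(unlist(cfg[1:4]) < 1L)) abort_domain("mpnn_config dimensions must be positive")
  structure(cfg, class = "mpnn_config")
}

#' Decoder configuration
#'
#' Defaults: three fully-connected layers of width 500 with LeakyReLU
#' activation, latent dimension d = 100.
#' @param n_layers,hidden,latent_dim Positive integers.
#' @param activation Activation name (`"leakyrelu"`).
#' @export
decoder_config <- function(n_layers = 3L, hidden = 500L, activation = "leakyrelu",
                           latent_dim = 100L) {
  cfg <- list(n_layers = as.integer(n_layers), hidden = as.integer(hidden),
              activation = activation, latent_dim = as.integer(latent_dim))
  if (cfg$n_layers < 1L || cfg$hidden < 1L || cfg$latent_dim < 1L)
    abort_domain("decoder_config dimensions must be positive")
  structure(cfg, class = "decoder_config")
}

# Parameters of one MPNN (embed + message/GRU layers + aggregation + head +
# a linear output), under a name prefix.
make_mpnn_params <- function(prefix, p, cfg, head_extra = 0L, out_dims = list()) {
  h <- cfg$message_hidden; ro <- cfg$readout_dim; hh <- cfg$head_hidden
  pm <- list()
  pm[[paste0(prefix, ".embed.W")]] <- glorot_matrix(p, h)
  pm[[paste0(prefix, ".embed.b")]] <- zeros_row(h)
  for (t in seq_len(cfg$n_message_layers)) {
    for (b in 1:3) pm[[sprintf("%s.msg%d.W%d", prefix, t, b)]] <- glorot_matrix(h, h)
    pm[[sprintf("%s.msg%d.b", prefix, t)]] <- zeros_row(h)
    for (nm in c("Wz", "Uz", "Wr", "Ur", "Wh", "Uh"))
      pm[[sprintf("%s.gru%d.%s", prefix, t, nm)]] <- glorot_matrix(h, h)
    for (nm in c("bz", "br", "bh"))
      pm[[sprintf("%s.gru%d.%s", prefix, t, nm)]] <- zeros_row(h)
  }
  pm[[paste0(prefix, ".agg.W")]] <- glorot_matrix(h, ro)
  pm[[paste0(prefix, ".agg.b")]] <- zeros_row(ro)
  pm[[paste0(prefix, ".head1.W")]] <- glorot_matrix(ro + head_extra, hh)
  pm[[paste0(prefix, ".head1.b")]] <- zeros_row(hh)
  pm[[paste0(prefix, ".head2.W")]] <- glorot_matrix(hh, hh)
  pm[[paste0(prefix, ".head2.b")]] <- zeros_row(hh)
  for (nm in names(out_dims)) {
    pm[[sprintf("%s.%s.W", prefix, nm)]] <- glorot_matrix(hh, out_dims[[nm]])
    pm[[sprintf("%s.%s.b", prefix, nm)]] <- zeros_row(out_dims[[nm]])
  }
  pm
}

make_decoder_params <- function(vocab, dcfg, l) {
  n_raw <- vocab$max_nodes * vocab$p + vocab$n_pairs * vocab$q
  pm <- list()
  nin <- dcfg$latent_dim + l
  for (t in seq_len(dcfg$n_layers)) {
    pm[[sprintf("dec.l%d.W", t)]] <- glorot_matrix(nin, dcfg$hidden)
    pm[[sprintf("dec.l%d.b", t)]] <- zeros_row(dcfg$hidden)
    nin <- dcfg$hidden
  }
  pm[["dec.out.W"]] <- glorot_matrix(dcfg$hidden, n_raw)
  pm[["dec.out.b"]] <- zeros_row(n_raw)
  pm
}

#' Initialize an untrained model
#'
#' Creates the encoder, decoder, reward and predictor networks (independent
#' parameter sets, Glorot-uniform initialization) over a vocabulary.
#'
#' @param vocab A [feature_vocabulary()].
#' @param mpnn_cfg,dec_cfg Network configurations.
#' @param l Property dimension (default 2: MolWt, LogP).
#' @param seed Integer seed for the weight initialization.
#' @return A `molgvae_model` list with fields `params`, `vocab`, `mpnn_cfg`,
#'   `dec_cfg`, `l`, `pairs`, `n_raw`, and (after training) `prior`.
#' @export
init_model <- function(vocab, mpnn_cfg = mpnn_config(), dec_cfg = decoder_config(),
                       l = 2L, seed = 1L) {
  set.seed(seed)
  d <- dec_cfg$latent_dim
  params <- c(
    make_mpnn_params("enc", vocab$p, mpnn_cfg, head_extra = l,
                     out_dims = list(mu = d, lv = d)),
    make_decoder_params(vocab, dec_cfg, l),
    make_mpnn_params("rew", vocab$p, mpnn_cfg, out_dims = list(out = 1L)),
    make_mpnn_params("prd", vocab$p, mpnn_cfg, out_dims = list(out = l))
  )
  structure(list(params = params, vocab = vocab, mpnn_cfg = mpnn_cfg,
                 dec_cfg = dec_cfg, l = as.integer(l),
                 pairs = pair_index(vocab$max_nodes),
                 n_raw = vocab$max_nodes * vocab$p + vocab$n_pairs * vocab$q,
                 prior = NULL),
            class = "molgvae_model")
}

#' @export
print.molgvae_model <- function(x, ...) {
  cat("<molgvae_model> m =", x$vocab$max_nodes, " d =", x$dec_cfg$latent_dim,
      " l =", x$l, " params =", length(x$params),
      if (is.null(x$prior)) "(untrained)" else "(with property prior)", "\n")
  invisible(x)
}

param_names_vae <- function(params) grep("^(enc|dec)\\.", names(params), value = TRUE)
param_names_aux <- function(params) grep("^(rew|prd)\\.", names(params), value = TRUE)

# ---- batching --------------------------------------------------------------

# Stack graphs/probabilistic graphs into batch matrices: node (B*m) x p,
# edge (B*n_pairs) x q in the fixed pair order.
stack_graphs <- function(objs, vocab, pairs = pair_index(vocab$max_nodes)) {
  B <- length(objs)
  m <- vocab$max_nodes; np <- nrow(pairs)
  node <- matrix(0, B * m, vocab$p)
  edge <- matrix(0, B * np, vocab$q)
  lin <- (pairs[, 2] - 1L) * m + pairs[, 1]
  for (g in seq_len(B)) {
    node[((g - 1L) * m + 1L):(g * m), ] <- objs[[g]]$node
    for (ch in seq_len(vocab$q)) {
      sl <- objs[[g]]$edge[, , ch]
      edge[((g - 1L) * np + 1L):(g * np), ch] <- sl[lin]
    }
  }
  list(node = node, edge = edge, B = B, m = m, np = np)
}

batch_const <- function(tp, stacked, pairs) {
  list(node = ad_const(tp, stacked$node), edge = ad_const(tp, stacked$edge),
       B = stacked$B, m = stacked$m, np = stacked$np,
       idx = edge_indices(stacked$B, stacked$m, pairs))
}

# ---- forward passes --------------------------------------------------------

# Shared MPNN trunk: returns the B x head_hidden representation.
nn_mpnn_head <- function(tp, pn, prefix, batch, cfg, vocab, pairs, extra = NULL) {
  P <- function(nm) pn[[paste0(prefix, ".", nm)]]
  B <- batch$B; m <- batch$m
  idx <- batch$idx
  if (is.null(idx)) idx <- edge_indices(B, m, pairs)
  ch_real <- match(c("single", "double", "triple"), vocab$bond_types)
  H <- ad_add_bias(ad_matmul(batch$node, P("embed.W"), tp), P("embed.b"), tp)
  for (t in seq_len(cfg$n_message_layers)) {
    Pm <- function(nm) pn[[sprintf("%s.msg%d.%s", prefix, t, nm)]]
    Pg <- function(nm) pn[[sprintf("%s.gru%d.%s", prefix, t, nm)]]
    M <- ad_edge_message3(ad_matmul(H, Pm("W1"), tp), ad_matmul(H, Pm("W2"), tp),
                          ad_matmul(H, Pm("W3"), tp), batch$edge, ch_real, idx, tp)
    M <- ad_add_bias(M, Pm("b"), tp)
    H <- ad_gru(M, H, Pg("Wz"), Pg("Uz"), Pg("Wr"), Pg("Ur"), Pg("Wh"), Pg("Uh"),
                Pg("bz"), Pg("br"), Pg("bh"), tp)
  }
  nodes_out <- ad_tanh(ad_add_bias(ad_matmul(H, P("agg.W"), tp), P("agg.b"), tp), tp)
  R <- ad_pool_sum(nodes_out, B, m, tp)
  if (!is.null(extra)) R <- ad_concat_cols(list(R, extra), tp)
  h1 <- ad_tanh(ad_add_bias(ad_matmul(R, P("head1.W"), tp), P("head1.b"), tp), tp)
  ad_tanh(ad_add_bias(ad_matmul(h1, P("head2.W"), tp), P("head2.b"), tp), tp)
}

# Encoder: (graphs, y) -> (mu, sigma2) nodes, each B x d.
nn_encoder <- function(tp, pn, batch, ynode, model) {
  h2 <- nn_mpnn_head(tp, pn, "enc", batch, model$mpnn_cfg, model$vocab, model$pairs,
                     extra = ynode)
  mu <- ad_add_bias(ad_matmul(h2, pn[["enc.mu.W"]], tp), pn[["enc.mu.b"]], tp)
  lv <- ad_clamp(ad_add_bias(ad_matmul(h2, pn[["enc.lv.W"]], tp), pn[["enc.lv.b"]], tp),
                 -10, 10, tp)
  list(mu = mu, sigma2 = ad_exp(lv, tp))
}

# Decoder: (z, y) nodes -> probabilistic-graph batch (node/edge prob nodes).
nn_decoder <- function(tp, pn, znode, ynode, model) {
  vocab <- model$vocab; dcfg <- model$dec_cfg
  x <- ad_concat_cols(list(znode, ynode), tp)
  for (t in seq_len(dcfg$n_layers)) {
    x <- ad_leaky_relu(ad_add_bias(ad_matmul(x, pn[[sprintf("dec.l%d.W", t)]], tp),
                                   pn[[sprintf("dec.l%d.b", t)]], tp), tp)
  }
  raw <- ad_add_bias(ad_matmul(x, pn[["dec.out.W"]], tp), pn[["dec.out.b"]], tp)
  m <- vocab$max_nodes; p <- vocab$p; np <- vocab$n_pairs; q <- vocab$q
  B <- nrow(raw$value)
  node_rows <- ad_blocks_to_rows(ad_slice_cols(raw, seq_len(m * p), tp), m, p, tp)
  atom <- ad_softmax_rows(ad_slice_cols(node_rows, vocab$atom_cols, tp), tp)
  chrg <- ad_softmax_rows(ad_slice_cols(node_rows, vocab$charge_cols, tp), tp)
  hyd <- ad_softmax_rows(ad_slice_cols(node_rows, vocab$h_cols, tp), tp)
  node <- ad_concat_cols(list(atom, chrg, hyd), tp)
  edge_rows <- ad_blocks_to_rows(ad_slice_cols(raw, m * p + seq_len(np * q), tp), np, q, tp)
  edge <- ad_softmax_rows(edge_rows, tp)
  list(node = node, edge = edge, B = B, m = m, np = np, raw = raw)
}

nn_reward <- function(tp, pn, batch, model) {
  h2 <- nn_mpnn_head(tp, pn, "rew", batch, model$mpnn_cfg, model$vocab, model$pairs)
  ad_sigmoid(ad_add_bias(ad_matmul(h2, pn[["rew.out.W"]], tp), pn[["rew.out.b"]], tp), tp)
}

nn_predictor <- function(tp, pn, batch, model) {
  h2 <- nn_mpnn_head(tp, pn, "prd", batch, model$mpnn_cfg, model$vocab, model$pairs)
  ad_add_bias(ad_matmul(h2, pn[["prd.out.W"]], tp), pn[["prd.out.b"]], tp)
}

# Param nodes for a tape (all parameters; updates are applied selectively).
param_nodes <- function(tp, params) {
  out <- list()
  for (nm in names(params)) out[[nm]] <- ad_param(tp, nm, params[[nm]])
  out
}

# Extract example g of a decoded probabilistic-graph batch as a
# probabilistic_graph object (diagonal edge slices one-hot on "none").
pg_from_batch <- function(pgb, g, vocab, pairs) {
  m <- vocab$max_nodes; np <- nrow(pairs)
  node <- pgb$node$value[((g - 1L) * m + 1L):(g * m), , drop = FALSE]
  ed <- pgb$edge$value[((g - 1L) * np + 1L):(g * np), , drop = FALSE]
  edge <- array(0, dim = c(m, m, vocab$q))
  edge[, , vocab$none_bond] <- diag(m)  # diagonal defaults; off-diagonal filled below
  for (ch in seq_len(vocab$q)) {
    sl <- edge[, , ch]
    sl[cbind(pairs[, 1], pairs[, 2])] <- ed[, ch]
    sl[cbind(pairs[, 2], pairs[, 1])] <- ed[, ch]
    edge[, , ch] <- sl
  }
  probabilistic_graph(node, edge, vocab, check = FALSE)
}

# ---- exported single-example surfaces --------------------------------------

#' Run an MPNN forward pass on a (probabilistic) graph
#'
#' Messages between nodes are weighted by the non-`"none"` edge-type
#' probabilities; the summation readout makes the output invariant to node
#' permutation. A one-hot [molecular_graph()] embedded via [one_hot()] is the
#' special case of a degenerate probabilistic graph.
#'
#' @param pg A `probabilistic_graph`.
#' @param config An [mpnn_config()].
#' @param out_dim Output dimension.
#' @param params Optional parameter list from [mpnn_init()]; created fresh
#'   (seeded) when omitted.
#' @param seed Seed used when `params` is omitted.
#' @return Numeric vector of length `out_dim`.
#' @export
mpnn_forward <- function(pg, config = mpnn_config(), out_dim, params = NULL, seed = 1L) {
  stopifnot(inherits(pg, "probabilistic_graph"))
  vocab <- pg$vocab
  if (is.null(params)) params <- mpnn_init(vocab$p, config, out_dim, seed)
  if (ncol(params[["mpnn.out.W"]]) != out_dim)
    abort_shape("params output dimension does not match out_dim")
  if (nrow(params[["mpnn.embed.W"]]) != vocab$p)
    abort_shape("params input dimension does not match the vocabulary")
  tp <- ad_tape()
  pn <- param_nodes(tp, params)
  pairs <- pair_index(vocab$max_nodes)
  batch <- batch_const(tp, stack_graphs(list(pg), vocab, pairs), pairs)
  h2 <- nn_mpnn_head(tp, pn, "mpnn", batch, config, vocab, pairs)
  out <- ad_add_bias(ad_matmul(h2, pn[["mpnn.out.W"]], tp), pn[["mpnn.out.b"]], tp)
  as.vector(out$value)
}

#' Initialize standalone MPNN parameters
#' @param p Node feature dimension of the vocabulary.
#' @param config An [mpnn_config()].
#' @param out_dim Output dimension.
#' @param seed Integer seed.
#' @export
mpnn_init <- function(p, config = mpnn_config(), out_dim, seed = 1L) {
  set.seed(seed)
  make_mpnn_params("mpnn", p, config, out_dims = list(out = out_dim))
}

#' Encode a molecular graph to the latent posterior
#'
#' @param model A `molgvae_model`.
#' @param g A [molecular_graph()] (or `probabilistic_graph`).
#' @param y Numeric property vector of length `model$l`, in normalized units.
#' @return List with `mu` and `sigma2` (both length d; `sigma2 > 0`).
#' @export
encode <- function(model, g, y) {
  if (inherits(g, "molecular_graph")) g <- one_hot(g)
  check_shape(length(y) == model$l, "property vector has wrong length")
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  batch <- batch_const(tp, stack_graphs(list(g), model$vocab, model$pairs), model$pairs)
  enc <- nn_encoder(tp, pn, batch, ad_const(tp, matrix(y, 1)), model)
  list(mu = as.vector(enc$mu$value), sigma2 = as.vector(enc$sigma2$value))
}

#' Reparameterized latent sample
#'
#' Implements the stated sampling form `mu + eps * sigma2` (the variance, not
#' the standard deviation, scales the noise); set `use_sigma = TRUE` for the
#' conventional `mu + eps * sigma` form.
#'
#' @param mu,sigma2 Numeric vectors of equal length, `sigma2 >= 0`.
#' @param eps Optional standard-normal vector (drawn when omitted).
#' @param use_sigma Scale by the standard deviation instead of the variance.
#' @return Numeric latent vector z.
#' @export
reparameterize <- function(mu, sigma2, eps = NULL, use_sigma = FALSE) {
  check_shape(length(mu) == length(sigma2), "mu and sigma2 must have equal length")
  if (is.null(eps)) eps <- stats::rnorm(length(mu))
  mu + eps * (if (use_sigma) sqrt(sigma2) else sigma2)
}

#' Decode a latent/property pair to a probabilistic graph
#'
#' The raw decoder output has exactly `m*p + m*(m-1)*q/2` values, softmaxed
#' per node block and per unordered node pair, then mirrored to a symmetric
#' edge tensor.
#'
#' @param model A `molgvae_model`.
#' @param z Latent vector (length d).
#' @param y Normalized property vector (length l).
#' @return A `probabilistic_graph`.
#' @export
decoder_forward <- function(model, z, y) {
  check_shape(length(z) == model$dec_cfg$latent_dim, "z has wrong length")
  check_shape(length(y) == model$l, "y has wrong length")
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  pgb <- nn_decoder(tp, pn, ad_const(tp, matrix(z, 1)), ad_const(tp, matrix(y, 1)), model)
  pg_from_batch(pgb, 1L, model$vocab, model$pairs)
}

#' Reward network forward pass
#' @param model A `molgvae_model`.
#' @param pg A `probabilistic_graph` (or [molecular_graph()]).
#' @return Predicted validity in (0, 1).
#' @export
reward_net_forward <- function(model, pg) {
  if (inherits(pg, "molecular_graph")) pg <- one_hot(pg)
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  batch <- batch_const(tp, stack_graphs(list(pg), model$vocab, model$pairs), model$pairs)
  as.numeric(nn_reward(tp, pn, batch, model)$value)
}

#' Property predictor forward pass
#' @param model A `molgvae_model`.
#' @param pg A `probabilistic_graph` (or [molecular_graph()]).
#' @return Numeric vector of length l (normalized property scale).
#' @export
predictor_forward <- function(model, pg) {
  if (inherits(pg, "molecular_graph")) pg <- one_hot(pg)
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  batch <- batch_const(tp, stack_graphs(list(pg), model$vocab, model$pairs), model$pairs)
  as.vector(nn_predictor(tp, pn, batch, model)$value)
}

# ---- persistence -----------------------------------------------------------

#' Save / load a model
#'
#' The model (all four networks' weights, vocabulary, configurations and the
#' property prior with its normalization statistics) is serialized with R's
#' native format plus a JSON manifest written alongside.
#'
#' @param model A `molgvae_model`.
#' @param path File path for the checkpoint (an `.json` manifest is written
#'   next to it).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  manifest <- list(package = "molgvae", class = "molgvae_model",
                   m = model$vocab$max_nodes, p = model$vocab$p, q = model$vocab$q,
                   l = model$l, latent_dim = model$dec_cfg$latent_dim,
                   n_params = length(model$params),
                   trained_prior = !is.null(model$prior))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "molgvae_model")) abort_format("not a molgvae model checkpoint")
  model
}
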