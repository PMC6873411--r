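# Joint optimization: per iteration a batch X is sampled, the encoder/decoder
# parameters (phi, theta) take a gradient step on J1, then the reward and
# predictor networks (r, f) take a step on J2 computed on the same batch from
# VAE outputs recomputed (without gradient) under the refreshed parameters.

#' Training configuration
#'
#' Defaults follow the study protocol: 50 epochs, RMSProp, learning rate
#' 0.0005, batch size 20, beta1 = beta2 = 1.
#'
#' @param epochs,batch_size Positive integers.
#' @param learning_rate Positive step size.
#' @param optimizer Only `"rmsprop"` is provided.
#' @param seed Integer seed controlling shuffling, latent draws and probes.
#' @param beta1,beta2 Loss trade-off weights.
#' @param use_sigma Use the conventional `mu + eps * sigma` reparameterization
#'   instead of the variance-scaled form (default FALSE).
#' @param clip Global gradient-norm clip (default 10).
#' @export
train_config <- function(epochs = 50L, batch_size = 20L, learning_rate = 5e-4,
                         optimizer = "rmsprop", seed = 1L, beta1 = 1, beta2 = 1,
                         use_sigma = FALSE, clip = 10) {
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    abort_domain("epochs, batch_size and learning_rate must be positive")
  if (!identical(optimizer, "rmsprop")) abort_domain("unsupported optimizer")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 use_sigma = isTRUE(use_sigma), clip = clip),
            class = "train_config")
}

#' Fit the property prior and normalization statistics
#'
#' Each property is normalized to mean 0 and standard deviation 1; the prior
#' p(y) = N(mu_y, Sigma_y) is the sample mean and covariance of the
#' normalized training properties. The normalization statistics are stored
#' with the prior (and persisted with the model).
#'
#' @param properties An n x l matrix/data.frame of property values in natural
#'   units, or a dataset list with a `properties` field.
#' @return An object of class `property_prior` with fields `mu`, `Sigma`,
#'   `center`, `scale`, `names`.
#' @export
fit_property_prior <- function(properties) {
  if (is.list(properties) && !is.null(properties$properties))
    properties <- properties$properties
  Y <- as.matrix(properties)
  if (nrow(Y) == 0L) abort_empty("cannot fit a property prior on an empty dataset")
  if (any(!is.finite(Y))) abort_domain("properties must be finite")
  center <- colMeans(Y)
  scale <- apply(Y, 2, stats::sd)
  if (any(scale == 0 | is.na(scale)))
    abort_degenerate("a property has zero variance; the prior is degenerate")
  Yn <- sweep(sweep(Y, 2, center), 2, scale, "/")
  structure(list(mu = colMeans(Yn), Sigma = stats::cov(Yn),
                 center = center, scale = scale,
                 names = colnames(Y) %||% paste0("y", seq_len(ncol(Y)))),
            class = "property_prior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.property_prior <- function(x, ...) {
  cat("<property_prior> l =", length(x$mu), " properties:",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

normalize_properties <- function(prior, Y) {
  sweep(sweep(as.matrix(Y), 2, prior$center), 2, prior$scale, "/")
}

denormalize_properties <- function(prior, Yn) {
  sweep(sweep(as.matrix(Yn), 2, prior$scale, "*"), 2, prior$center, "+")
}

# Forward-only VAE pass (no gradients): encoder -> z -> decoder on the data
# batch plus the prior-draw decoder pass; returns decoder output values and
# decoded external rewards for the J2 labels.
vae_forward_values <- function(model, graphs, Y, draws, use_sigma = FALSE) {
  vocab <- model$vocab; pairs <- model$pairs
  B <- length(graphs)
  tp <- ad_tape()
  pn <- param_nodes(tp, model$params)
  batch <- batch_const(tp, stack_graphs(lapply(graphs, one_hot), vocab, pairs), pairs)
  ynode <- ad_const(tp, Y)
  enc <- nn_encoder(tp, pn, batch, ynode, model)
  sc <- if (use_sigma) sqrt(enc$sigma2$value) else enc$sigma2$value
  z_all <- ad_const(tp, rbind(enc$mu$value + draws$eps * sc, draws$z_prior))
  y_all <- ad_const(tp, rbind(Y, draws$y_prior))
  pgb <- nn_decoder(tp, pn, z_all, y_all, model)
  Rv <- decode_validity_pgb(pgb, vocab, pairs)
  list(soft_vals = list(node = pgb$node$value, edge = pgb$edge$value),
       R_recon = Rv[seq_len(B)], R_prior = Rv[B + seq_len(B)])
}

#' Train the graph VAE with its auxiliary networks
#'
#' Runs the joint loop: for each batch, a J1 gradient step on the
#' encoder/decoder, then a J2 step on the reward and predictor networks, both
#' every iteration. Deterministic given the configuration seed.
#'
#' @param dataset A list with `graphs` (list of [molecular_graph()]) and
#'   `properties` (n x l matrix, natural units), as returned by
#'   [load_dataset()] / [fixture_dataset()].
#' @param train_cfg A [train_config()].
#' @param mpnn_cfg,dec_cfg Network configurations (used when `model` is NULL).
#' @param model Optional `molgvae_model` to continue training (its property
#'   prior and normalization statistics are reused).
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @param log_file Optional path; per-epoch records are appended as JSON lines.
#' @param probe_n Per-epoch validity probe size (0 disables; default 100).
#' @param epoch_hook Optional `function(epoch, model)` called after each
#'   epoch (e.g. to snapshot generation quality mid-run).
#' @return List with `model` (trained) and `log` (one row per epoch with the
#'   mean per-term losses and the probe validity).
#' @export
train_model <- function(dataset, train_cfg = train_config(),
                        mpnn_cfg = mpnn_config(), dec_cfg = decoder_config(),
                        model = NULL, checkpoint_dir = NULL, log_file = NULL,
                        probe_n = 100L, epoch_hook = NULL) {
  graphs <- dataset$graphs
  n <- length(graphs)
  if (n == 0L) abort_empty("empty training dataset")
  props <- as.matrix(dataset$properties)
  l <- ncol(props)
  if (is.null(model)) {
    vocab <- graphs[[1]]$vocab
    model <- init_model(vocab, mpnn_cfg, dec_cfg, l = l, seed = train_cfg$seed)
    model$prior <- fit_property_prior(props)
  } else if (is.null(model$prior)) {
    model$prior <- fit_property_prior(props)
  }
  prior <- model$prior
  Yall <- normalize_properties(prior, props)
  weights <- loss_weights(train_cfg$beta1, train_cfg$beta2)
  aux_active <- train_cfg$beta1 > 0 || train_cfg$beta2 > 0
  vae_names <- param_names_vae(model$params)
  aux_names <- param_names_aux(model$params)
  opt_vae <- list(); opt_aux <- list()
  set.seed(train_cfg$seed)
  log_rows <- vector("list", train_cfg$epochs)
  part_names <- c("recon", "kl", "rl_vae", "prop_vae", "rl_reward", "prop_pred")

  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = train_cfg$batch_size)
    sums <- stats::setNames(numeric(length(part_names)), part_names)
    n_batches <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + train_cfg$batch_size - 1L, n)]
      bg <- graphs[idx]
      Y <- Yall[idx, , drop = FALSE]
      draws <- make_draws(model, length(idx), prior)
      j1 <- j1_tape(model, bg, Y, weights, draws, use_sigma = train_cfg$use_sigma)
      ad_backward(j1$tp, j1$loss)
      st <- rmsprop_step(model$params, ad_grads(j1$tp), opt_vae, vae_names,
                         lr = train_cfg$learning_rate, clip = train_cfg$clip)
      model$params <- st$params; opt_vae <- st$state
      if (aux_active) {
        fw <- vae_forward_values(model, bg, Y, draws, use_sigma = train_cfg$use_sigma)
        j2 <- j2_tape(model, bg, Y, weights, fw$soft_vals, fw$R_recon, fw$R_prior)
        ad_backward(j2$tp, j2$loss)
        st <- rmsprop_step(model$params, ad_grads(j2$tp), opt_aux, aux_names,
                           lr = train_cfg$learning_rate, clip = train_cfg$clip)
        model$params <- st$params; opt_aux <- st$state
        sums[names(j2$parts)] <- sums[names(j2$parts)] + j2$parts
      }
      sums[names(j1$parts)] <- sums[names(j1$parts)] + j1$parts
      n_batches <- n_batches + 1L
    }
    probe_validity <- NA_real_
    if (probe_n > 0L) {
      Yn <- sample_y_unconditional(prior, probe_n)
      z <- matrix(stats::rnorm(probe_n * model$dec_cfg$latent_dim),
                  probe_n, model$dec_cfg$latent_dim)
      tp <- ad_tape()
      pgb <- nn_decoder(tp, param_nodes(tp, model$params),
                        ad_const(tp, z), ad_const(tp, Yn), model)
      probe_validity <- mean(decode_validity_pgb(pgb, model$vocab, model$pairs))
    }
    row <- c(list(epoch = epoch), as.list(sums / n_batches),
             list(probe_validity = probe_validity))
    log_rows[[epoch]] <- row
    if (!is.null(log_file))
      cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE)
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_model(model, file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
    }
    if (!is.null(epoch_hook)) epoch_hook(epoch, model)
  }
  log <- do.call(rbind, lapply(log_rows, function(r) as.data.frame(r)))
  list(model = model, log = log)
}
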