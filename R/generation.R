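# Molecular graph generation: draw y (from the prior, or from the Gaussian
# conditional given a target property value), draw z from the standard-normal
# latent prior, run the decoder, and discretize by node/edge-wise argmax.
# Generation never fails: invalid decoded graphs flow through to evaluation.

#' Sample property vectors from the prior
#'
#' @param prior A `property_prior`.
#' @param n Number of draws.
#' @return n x l matrix in normalized property space.
#' @export
sample_y_unconditional <- function(prior, n) {
  stopifnot(inherits(prior, "property_prior"))
  Y <- MASS::mvrnorm(n, mu = prior$mu, Sigma = prior$Sigma)
  Y <- matrix(Y, nrow = n)
  colnames(Y) <- prior$names
  Y
}

#' Sample property vectors conditioned on one coordinate
#'
#' Draws from the Gaussian conditional of N(mu_y, Sigma_y) given `y[k] = tau`,
#' using the closed form: conditional mean
#' `mu_{-k} + Sigma_{-k,k} (tau_n - mu_k) / Sigma_{k,k}` and covariance
#' `Sigma_{-k,-k} - Sigma_{-k,k} Sigma_{k,-k} / Sigma_{k,k}`. The target
#' `tau` is given in natural units and converted with the stored
#' normalization statistics; coordinate `k` of every draw equals the
#' normalized target exactly.
#'
#' @param prior A `property_prior`.
#' @param k Property index (integer) or name.
#' @param tau Target value in natural units.
#' @param n Number of draws.
#' @return n x l matrix in normalized property space, with attributes
#'   `condition_k` and `condition_tau` (natural units).
#' @export
sample_y_conditional <- function(prior, k, tau, n) {
  stopifnot(inherits(prior, "property_prior"))
  if (is.character(k)) k <- match(k, prior$names)
  l <- length(prior$mu)
  if (is.na(k) || k < 1L || k > l) abort_domain("unknown property index")
  S <- prior$Sigma
  if (S[k, k] <= 0) abort_degenerate("conditioning coordinate has zero variance")
  tau_n <- (tau - prior$center[k]) / prior$scale[k]
  Y <- matrix(0, n, l)
  rest <- setdiff(seq_len(l), k)
  if (length(rest) > 0) {
    mu_c <- prior$mu[rest] + S[rest, k] * (tau_n - prior$mu[k]) / S[k, k]
    S_c <- S[rest, rest, drop = FALSE] -
      tcrossprod(S[rest, k, drop = FALSE]) / S[k, k]
    Y[, rest] <- matrix(MASS::mvrnorm(n, mu = mu_c, Sigma = S_c), nrow = n)
  }
  Y[, k] <- tau_n
  colnames(Y) <- prior$names
  attr(Y, "condition_k") <- k
  attr(Y, "condition_tau") <- tau
  Y
}

# Decoder pass over normalized property rows; z ~ N(0, I) from the current
# RNG stream. Returns decoded graphs (and optionally the soft graphs).
generate_core <- function(model, Yn, batch_size = 100L, keep_pg = FALSE) {
  n <- nrow(Yn)
  d <- model$dec_cfg$latent_dim
  graphs <- vector("list", n)
  pgs <- if (keep_pg) vector("list", n) else NULL
  done <- 0L
  while (done < n) {
    B <- min(batch_size, n - done)
    z <- matrix(stats::rnorm(B * d), B, d)
    tp <- ad_tape()
    pn <- param_nodes(tp, model$params)
    pgb <- nn_decoder(tp, pn, ad_const(tp, z),
                      ad_const(tp, Yn[done + seq_len(B), , drop = FALSE]), model)
    for (g in seq_len(B)) {
      pg <- pg_from_batch(pgb, g, model$vocab, model$pairs)
      graphs[[done + g]] <- decode_graph(pg)
      if (keep_pg) pgs[[done + g]] <- pg
    }
    done <- done + B
  }
  list(graphs = graphs, pgs = pgs)
}

#' Generate molecular graphs from a trained model
#'
#' For each sample, y is drawn from the property prior (or its conditional
#' given `condition`), z from N(0, I), and the decoder output is discretized
#' by argmax. All n results are returned, including chemically invalid ones;
#' validity is judged downstream by [evaluate_generation()].
#'
#' @param model A trained `molgvae_model` (with property prior).
#' @param n Number of samples.
#' @param condition Optional target condition: a named scalar such as
#'   `c(molwt = 350)` or a list with `k` and `tau` (natural units).
#' @param seed Optional integer seed.
#' @param batch_size Decoder batch size.
#' @param keep_pg Keep the raw probabilistic graphs (memory-heavy).
#' @return A `generation_result`: `graphs`, `validity` (0/1 per sample),
#'   `y_norm`, `y_natural`, `condition`, and optionally `pgs`.
#' @export
generate_molecules <- function(model, n, condition = NULL, seed = NULL,
                               batch_size = 100L, keep_pg = FALSE) {
  if (is.null(model$prior)) abort_domain("model has no property prior; train first")
  if (!is.null(seed)) set.seed(seed)
  prior <- model$prior
  cond <- NULL
  if (is.null(condition)) {
    Yn <- sample_y_unconditional(prior, n)
  } else {
    if (is.list(condition)) {
      k <- condition$k; tau <- condition$tau
    } else {
      k <- names(condition)[1]; tau <- as.numeric(condition[1])
    }
    Yn <- sample_y_conditional(prior, k, tau, n)
    cond <- list(k = attr(Yn, "condition_k"), tau = tau,
                 name = prior$names[attr(Yn, "condition_k")])
  }
  core <- generate_core(model, Yn, batch_size = batch_size, keep_pg = keep_pg)
  structure(list(graphs = core$graphs,
                 validity = vapply(core$graphs, validity_reward, numeric(1)),
                 y_norm = Yn, y_natural = denormalize_properties(prior, Yn),
                 condition = cond, pgs = core$pgs),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result>", length(x$graphs), "samples,",
      sum(x$validity), "valid",
      if (!is.null(x$condition))
        sprintf(" | condition %s = %g", x$condition$name, x$condition$tau) else "",
      "\n")
  invisible(x)
}
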