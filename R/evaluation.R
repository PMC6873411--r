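# Generation quality metrics: Validity (fraction of generated graphs passing
# the sanitization reward), Uniqueness (fraction of valid graphs that are not
# duplicates), Novelty (fraction of valid graphs absent from the training
# set), and their geometric mean (G-mean), plus the conditional-generation
# property summaries.

#' Geometric mean of validity, uniqueness and novelty
#' @param validity,uniqueness,novelty Values in [0, 1].
#' @return `(validity * uniqueness * novelty)^(1/3)`.
#' @export
g_mean <- function(validity, uniqueness, novelty) {
  (validity * uniqueness * novelty)^(1 / 3)
}

#' Evaluate a sample of generated molecular graphs
#'
#' Validity is counted over all n samples; uniqueness and novelty over the
#' valid ones. Novelty's denominator includes duplicate valid graphs (the
#' literal fraction of valid graphs not contained in the training set); set
#' `novelty_over_unique = TRUE` to divide by the unique-valid count instead,
#' for comparison with toolkits using that convention. Property statistics
#' (MolWt, LogP mean and sd) are computed over the valid unique molecules.
#'
#' @param generated A `generation_result` from [generate_molecules()], or a
#'   list of [molecular_graph()] objects.
#' @param training_keys Character vector of canonical keys of the training
#'   molecules (built with the same canonicalization as [canonical_key()]).
#' @param novelty_over_unique Alternative novelty denominator (default FALSE).
#' @return A `generation_report`: `n_sampled`, `validity`, `uniqueness`,
#'   `novelty`, `g_mean`, `unique_count`, `property_stats` (data.frame with
#'   mean/sd per property), `unique_keys`.
#' @export
evaluate_generation <- function(generated, training_keys = character(0),
                                novelty_over_unique = FALSE) {
  graphs <- if (inherits(generated, "generation_result")) generated$graphs else generated
  n <- length(graphs)
  if (n == 0L) abort_empty("no generated graphs to evaluate")
  valid <- vapply(graphs, validity_reward, numeric(1))
  n_valid <- sum(valid)
  validity <- n_valid / n
  uniqueness <- 0; novelty <- 0; unique_count <- 0L
  keys <- character(0); ukeys <- character(0)
  if (n_valid > 0) {
    keys <- canonical_keys(graphs[valid == 1])
    keys <- keys[!is.na(keys)]
    ukeys <- unique(keys)
    unique_count <- length(ukeys)
    uniqueness <- unique_count / n_valid
    novelty <- if (novelty_over_unique) {
      sum(!(ukeys %in% training_keys)) / max(1L, unique_count)
    } else {
      sum(!(keys %in% training_keys)) / n_valid
    }
  }
  gm <- g_mean(validity, uniqueness, novelty)
  prop_stats <- NULL
  if (unique_count > 0) {
    pr <- properties_from_smiles(ukeys)
    sd0 <- function(x) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = TRUE)
    prop_stats <- data.frame(
      property = c("molwt", "logp"),
      mean = c(mean(pr$molwt, na.rm = TRUE), mean(pr$logp, na.rm = TRUE)),
      sd = c(sd0(pr$molwt), sd0(pr$logp))
    )
  }
  structure(list(n_sampled = n, validity = validity, uniqueness = uniqueness,
                 novelty = novelty, g_mean = gm, unique_count = unique_count,
                 property_stats = prop_stats, unique_keys = ukeys),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  fmt <- function(v) formatC(round(v, 3), format = "f", digits = 3)
  cat("<generation_report> n =", x$n_sampled, "\n")
  cat(sprintf("  validity %s  uniqueness %s  novelty %s  G-mean %s  unique %d\n",
              fmt(x$validity), fmt(x$uniqueness), fmt(x$novelty), fmt(x$g_mean),
              x$unique_count))
  if (!is.null(x$property_stats)) {
    for (r in seq_len(nrow(x$property_stats)))
      cat(sprintf("  %s %.2f +/- %.2f\n", x$property_stats$property[r],
                  x$property_stats$mean[r], x$property_stats$sd[r]))
  }
  invisible(x)
}

#' Conditional-generation summary row
#'
#' The conditional summary schema: target condition, G-mean, unique count,
#' and MolWt / LogP mean and sd over the valid unique molecules.
#'
#' @param generated A `generation_result` carrying condition metadata (or any
#'   input accepted by [evaluate_generation()] together with `condition`).
#' @param training_keys Canonical keys of the training set.
#' @param condition Optional override: list with `name` and `tau`.
#' @return A one-row data.frame: `condition`, `g_mean`, `unique_count`,
#'   `molwt_mean`, `molwt_sd`, `logp_mean`, `logp_sd`.
#' @export
conditional_report <- function(generated, training_keys = character(0),
                               condition = NULL) {
  if (is.null(condition) && inherits(generated, "generation_result"))
    condition <- generated$condition
  rep <- evaluate_generation(generated, training_keys)
  ps <- rep$property_stats
  get <- function(prop, col) {
    if (is.null(ps)) NA_real_ else ps[[col]][ps$property == prop]
  }
  data.frame(
    condition = if (is.null(condition)) "unconditional"
                else sprintf("%s = %g", condition$name, condition$tau),
    g_mean = rep$g_mean,
    unique_count = rep$unique_count,
    molwt_mean = get("molwt", "mean"), molwt_sd = get("molwt", "sd"),
    logp_mean = get("logp", "mean"), logp_sd = get("logp", "sd")
  )
}
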