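# Classed error conditions used throughout the package. Each helper raises a
# condition inheriting from c("molgvae_<class>", "molgvae_error", "error") so
# callers can catch a specific failure mode without string matching.

molgvae_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("molgvae_", class), "molgvae_error")))
}

abort_vocabulary <- function(msg, ...) molgvae_abort("vocabulary_error", msg, ...)
abort_size <- function(msg, ...) molgvae_abort("size_error", msg, ...)
abort_kekulization <- function(msg, ...) molgvae_abort("kekulization_error", msg, ...)
abort_canonicalization <- function(msg, ...) molgvae_abort("canonicalization_error", msg, ...)
abort_shape <- function(msg, ...) molgvae_abort("shape_error", msg, ...)
abort_domain <- function(msg, ...) molgvae_abort("domain_error", msg, ...)
abort_degenerate <- function(msg, ...) molgvae_abort("degenerate_error", msg, ...)
abort_format <- function(msg, ...) molgvae_abort("format_error", msg, ...)
abort_exhaustion <- function(msg, ...) molgvae_abort("exhaustion_error", msg, ...)
abort_empty <- function(msg, ...) molgvae_abort("empty_error", msg, ...)

check_shape <- function(ok, msg) {
  if (!isTRUE(ok)) abort_shape(msg)
  invisible(TRUE)
}
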