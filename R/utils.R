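#' @importFrom rlang .data abort warn
#' @importFrom stats dnorm prcomp rnorm runif sd setNames var
#' @importFrom utils head tail
NULL

# Boltzmann constant in kcal/(mol K), the unit used for all free energies.
KB_KCAL <- 0.0019872

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# smallest signed angular difference in degrees, in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (frame sampling, noise injection, reference-spectrum noise) draw
#' from seeds derived deterministically with this splitter, so adding a
#' stage never perturbs the stream of another.
#'
#' @param seed master integer seed.
#' @param stage small non-negative integer identifying the consumer.
#' @return an integer seed below 2^31.
#' @export
split_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * (stage + 1)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopif_not_spectrum <- function(s, arg = deparse(substitute(s))) {
  if (!is.data.frame(s) || !all(c("wavenumber", "intensity") %in% names(s))) {
    abort(paste0("`", arg, "` must be a data frame with columns `wavenumber` and `intensity`"))
  }
  if (is.unsorted(s$wavenumber, strictly = TRUE)) {
    abort(paste0("`", arg, "`: wavenumber grid must be strictly increasing"))
  }
  invisible(s)
}
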