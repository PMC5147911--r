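## Per-base sequencing error profiles for the two platforms.
##
## Rates are free parameters of the study, chosen order-of-magnitude
## realistic for a low-error short-read chemistry and a high-error
## single-molecule long-read chemistry whose dominant failure mode is
## deletion inside homopolymer runs of five or more identical bases.

#' Construct a per-base error profile
#'
#' @param substitution,insertion,deletion per-base error probabilities.
#' @param homopolymer_extra_deletion additional per-base deletion probability
#'   applied only inside annotated homopolymer runs of length >= 5.
#' @return An `error_profile` list.
#' @export
error_profile <- function(substitution = 0, insertion = 0, deletion = 0,
                          homopolymer_extra_deletion = 0) {
  rates <- c(substitution = substitution, insertion = insertion,
             deletion = deletion,
             homopolymer_extra_deletion = homopolymer_extra_deletion)
  if (any(rates < 0 | rates > 1))
    stop_config("error rates must lie in [0, 1]")
  structure(as.list(rates), class = "error_profile")
}

#' Default short-read (deep, low-error) profile
#' @return An `error_profile`.
#' @export
short_error_profile <- function() {
  error_profile(substitution = 0.002, insertion = 1e-4, deletion = 1e-4,
                homopolymer_extra_deletion = 0)
}

#' Default long-read (high-error, homopolymer-sensitive) profile
#' @return An `error_profile`.
#' @export
long_error_profile <- function() {
  error_profile(substitution = 0.05, insertion = 0.04, deletion = 0.05,
                homopolymer_extra_deletion = 0.15)
}

#' Zero-error profile (for round-trip checks)
#' @return An `error_profile`.
#' @export
zero_error_profile <- function() error_profile()

## Constant base qualities by platform: the long-read chemistry's scores do
## not follow a phred scale, so the caller uses a depth floor instead of
## quality weighting and the simulator emits explicit constants.
QUAL_SHORT <- 35L
QUAL_LONG <- 10L
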