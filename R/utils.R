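#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif setNames aggregate median quantile
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Default seed used wherever a seed argument is optional.
DEFAULT_SEED <- 1001L

#' Derive a stage seed from a global seed
#'
#' Deterministic, collision-free-enough mapping of (global seed, stage offset)
#' onto the 32-bit seed space, so every stochastic stage of a pipeline run
#' receives its own reproducible stream.
#'
#' @param seed integer global seed.
#' @param offset small integer stage index.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483647)
}

## paste keys used to compare variant calls as sets
variant_key <- function(pos, alt) {
  if (!length(pos)) return(character(0))
  paste0(pos, ":", alt)
}

## round to 3 decimals, banker's (half-even) rounding -- base round() is
## half-even already; kept as a named helper so the reporting rule is explicit
round_metric <- function(x) round(x, 3)

## whole-percent reporting as used in allele-count tables
as_percent <- function(x) as.integer(round(100 * x))

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

random_bases <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

## substitute each base for one of the three others, uniformly
substitute_bases <- function(bases) {
  offs <- sample.int(3L, length(bases), replace = TRUE)
  idx <- match(bases, DNA_BASES)
  DNA_BASES[((idx - 1L + offs) %% 4L) + 1L]
}

stop_config <- function(...) stop(..., call. = FALSE)
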