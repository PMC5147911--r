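## Synthetic circular reference with two-amplicon geometry.
##
## The genome emulates a human-mitochondrion-sized circular molecule enriched
## by two overlapping long-PCR amplicons (~8.3 kb and ~8.6 kb at full size;
## scaled proportionally for smaller test genomes). In the real molecule the
## second amplicon spans the replication origin; here the reference is
## reported in rotated coordinates with the cut placed inside that
## origin-spanning overlap, so both amplicons are contiguous intervals and no
## read wraps. One interior overlap (~331 bp at full size) remains between
## amplicon 1's start and amplicon 2's end; the second overlap survives as
## the junction between position 0 and position L-1 on the circle.

AMP1_FRAC <- 8300 / 16569   # amplicon 1 length as fraction of genome
AMP2_FRAC <- 8600 / 16569   # amplicon 2 (origin-spanning) fraction
PRIMER_LEN <- 25L
EDGE_MARGIN <- 300L         # linear-end margin excluded from variant placement

#' Generate a circular reference genome with planted homopolymer runs
#'
#' Builds a random A/C/G/T genome, plants `n_homopolymers` non-overlapping
#' runs of at least `min_run` identical bases at recorded positions, and
#' attaches the two-amplicon enrichment geometry (amplicon 2 at `[0, ~8.6kb)`,
#' amplicon 1 ending at the genome end, overlapping in the interior).
#'
#' @param length genome length in bp (>= 1000).
#' @param n_homopolymers number of runs to plant.
#' @param min_run minimum run length (>= 5; the long-read error model only
#'   applies its extra deletion rate inside runs of at least 5).
#' @param seed integer seed; identical inputs and seed give identical genomes.
#' @return An object of class `mito_reference`: list with `name`, `sequence`,
#'   `length`, `circular`, `homopolymers` (data frame start/length/base,
#'   0-based starts), `amplicons` (data frame with 0-based half-open
#'   start/end and primer intervals), and `rotation` (bp by which the
#'   original circular coordinates were rotated).
#' @export
generate_reference <- function(length = 16569L, n_homopolymers = 3L,
                               min_run = 6L, seed = DEFAULT_SEED) {
  length <- as.integer(length)
  if (length < 1000L)
    stop_config("genome length ", length, " too small to host the amplicons")
  if (min_run < 5L)
    stop_config("min_run must be >= 5 (homopolymer error mode threshold)")

  a1len <- as.integer(round(length * AMP1_FRAC))
  a2len <- as.integer(round(length * AMP2_FRAC))
  if (a1len <= 2L * PRIMER_LEN || a2len <= 2L * PRIMER_LEN)
    stop_config("genome length ", length, " too small to host the amplicons")

  withr::with_seed(seed, {
    seq_chars <- random_bases(length)

    ## plant non-overlapping homopolymer runs away from the linear ends
    hp <- data.frame(start = integer(0), length = integer(0),
                     base = character(0), stringsAsFactors = FALSE)
    if (n_homopolymers > 0) {
      lo <- EDGE_MARGIN + PRIMER_LEN
      hi <- length - EDGE_MARGIN - PRIMER_LEN - min_run - 4L
      if (hi <= lo)
        stop_config("genome too small to place ", n_homopolymers, " runs")
      taken <- integer(0)
      for (i in seq_len(n_homopolymers)) {
        placed <- FALSE
        for (try in 1:200) {
          run_len <- min_run + sample.int(4L, 1L) - 1L
          s <- lo + sample.int(hi - lo, 1L)
          if (!any(abs(s - taken) < (run_len + min_run + 10L))) {
            b <- sample(DNA_BASES, 1L)
            seq_chars[(s + 1L):(s + run_len)] <- b
            hp <- rbind(hp, data.frame(start = s, length = run_len, base = b,
                                       stringsAsFactors = FALSE))
            taken <- c(taken, s)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop_config("could not place ", n_homopolymers,
                      " non-overlapping homopolymer runs")
      }
      hp <- hp[order(hp$start), , drop = FALSE]
      rownames(hp) <- NULL
    }

    amplicons <- data.frame(
      name = c("amp2", "amp1"),
      start = c(0L, length - a1len),
      end = c(a2len, length),
      primer1_start = c(0L, length - a1len),
      primer1_end = c(PRIMER_LEN, length - a1len + PRIMER_LEN),
      primer2_start = c(a2len - PRIMER_LEN, length - PRIMER_LEN),
      primer2_end = c(a2len, length),
      stringsAsFactors = FALSE
    )

    ref <- structure(list(
      name = "chrM_synthetic",
      sequence = paste(seq_chars, collapse = ""),
      length = length,
      circular = TRUE,
      homopolymers = hp,
      amplicons = amplicons,
      rotation = as.integer(round(length * 8780 / 16569))
    ), class = "mito_reference")
    ref
  })
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("mito_reference '", x$name, "': ", x$length, " bp, circular; ",
      nrow(x$homopolymers), " planted homopolymer run(s); amplicons ",
      paste(sprintf("%s[%d,%d)", x$amplicons$name, x$amplicons$start,
                    x$amplicons$end), collapse = ", "), "\n", sep = "")
  invisible(x)
}

ref_chars <- function(ref) strsplit(ref$sequence, "", fixed = TRUE)[[1]]

## logical mask over [0, L): TRUE inside an annotated homopolymer run >= 5
homopolymer_mask <- function(ref) {
  mask <- logical(ref$length)
  hp <- ref$homopolymers
  if (nrow(hp)) {
    for (i in seq_len(nrow(hp))) {
      if (hp$length[i] >= 5L)
        mask[(hp$start[i] + 1L):(hp$start[i] + hp$length[i])] <- TRUE
    }
  }
  mask
}

## union of primer intervals as 0-based positions
primer_positions <- function(ref) {
  a <- ref$amplicons
  unlist(lapply(seq_len(nrow(a)), function(i) {
    c(seq.int(a$primer1_start[i], a$primer1_end[i] - 1L),
      seq.int(a$primer2_start[i], a$primer2_end[i] - 1L))
  }))
}

#' Write the reference as FASTA
#' @param ref a `mito_reference`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

validate_reference <- function(ref) {
  stopifnot(ref$length > 0,
            grepl("^[ACGT]+$", ref$sequence),
            nchar(ref$sequence) == ref$length)
  hp <- ref$homopolymers
  if (nrow(hp)) {
    chars <- ref_chars(ref)
    for (i in seq_len(nrow(hp))) {
      run <- chars[(hp$start[i] + 1L):(hp$start[i] + hp$length[i])]
      stopifnot(hp$start[i] >= 0, hp$start[i] + hp$length[i] <= ref$length,
                all(run == hp$base[i]))
    }
  }
  invisible(TRUE)
}
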