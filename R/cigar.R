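## CIGAR machinery.
##
## Reads are carried through the pipeline as plain data frames with 0-based
## reference starts and CIGAR strings restricted to the ops M, I, D and S.
## The base-at-reference-offset walk implemented here is the primitive the
## phasing and deconvolution stages are built on.

CIGAR_QUERY_OPS <- c("M", "I", "S")
CIGAR_REF_OPS <- c("M", "D")

#' Parse CIGAR strings
#'
#' @param cigars character vector of CIGAR strings (ops M, I, D, S).
#' @return A list, one element per input, each a list with integer `len` and
#'   character `op` vectors. Parsing is cached over unique strings, so large
#'   read sets dominated by a single CIGAR (e.g. `"250M"`) parse in O(unique).
#' @export
parse_cigar <- function(cigars) {
  u <- unique(cigars)
  m <- gregexpr("([0-9]+)([MIDS])", u)
  parsed <- lapply(seq_along(u), function(i) {
    toks <- regmatches(u[i], m[i])[[1]]
    if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(u[i]))
      stop("malformed CIGAR: ", u[i])
    list(len = as.integer(sub("[MIDS]$", "", toks)),
         op = sub("^[0-9]+", "", toks))
  })
  parsed[match(cigars, u)]
}

cigar_query_length <- function(parsed) {
  vapply(parsed, function(p) sum(p$len[p$op %in% CIGAR_QUERY_OPS]), integer(1))
}

cigar_ref_span <- function(parsed) {
  vapply(parsed, function(p) sum(p$len[p$op %in% CIGAR_REF_OPS]), integer(1))
}

## Build a compact CIGAR string from per-base op labels (already ordered).
cigar_from_ops <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Validate CIGAR/sequence consistency of a read table
#'
#' Checks, for every read, that the query-consuming CIGAR length equals the
#' sequence length and that the reference span stays inside the genome.
#'
#' @param reads a read data frame (see [simulate_short_reads()]).
#' @param ref a [generate_reference()] genome.
#' @return Invisibly `TRUE`; errors on the first inconsistent read.
#' @export
validate_reads <- function(reads, ref) {
  if (nrow(reads) == 0) return(invisible(TRUE))
  parsed <- parse_cigar(reads$cigar)
  qlen <- cigar_query_length(parsed)
  bad <- which(qlen != nchar(reads$seq))
  if (length(bad))
    stop("CIGAR/sequence length mismatch for read ", reads$read_id[bad[1]])
  span <- cigar_ref_span(parsed)
  bad <- which(reads$ref_start < 0 | reads$ref_start + span > ref$length)
  if (length(bad))
    stop("read extends past reference end: ", reads$read_id[bad[1]])
  invisible(TRUE)
}

## Walk one read's CIGAR to the base covering 0-based reference position pos.
## Returns list(op=, base=): op is the covering CIGAR op ("M" or "D"), or NA
## if the read does not cover pos; base is the read base when op == "M".
read_base_at <- function(ref_start, parsed, seq, pos) {
  rp <- ref_start
  qp <- 0L
  for (k in seq_along(parsed$op)) {
    op <- parsed$op[k]
    len <- parsed$len[k]
    if (op == "M") {
      if (pos >= rp && pos < rp + len) {
        return(list(op = "M", base = substr(seq, qp + (pos - rp) + 1L,
                                            qp + (pos - rp) + 1L)))
      }
      rp <- rp + len
      qp <- qp + len
    } else if (op == "D") {
      if (pos >= rp && pos < rp + len) return(list(op = "D", base = NA_character_))
      rp <- rp + len
    } else { # I, S consume query only
      qp <- qp + len
    }
  }
  list(op = NA_character_, base = NA_character_)
}

#' Bases observed at one reference position across many reads
#'
#' Vectorised base-at-offset query: for each read whose reference span covers
#' `pos`, report the covering CIGAR op and (for M) the read base. Reads whose
#' CIGAR is a single M run take a fast path.
#'
#' @param reads read data frame.
#' @param pos 0-based reference position.
#' @return data frame with columns `idx` (row index into `reads`), `op`,
#'   `base`; one row per read covering `pos`.
#' @export
bases_at_position <- function(reads, pos) {
  parsed <- parse_cigar(reads$cigar)
  span <- cigar_ref_span(parsed)
  cov <- which(reads$ref_start <= pos & pos < reads$ref_start + span)
  if (!length(cov)) {
    return(data.frame(idx = integer(0), op = character(0),
                      base = character(0), stringsAsFactors = FALSE))
  }
  pureM <- vapply(parsed[cov], function(p) length(p$op) == 1L && p$op == "M",
                  logical(1))
  op <- character(length(cov))
  base <- character(length(cov))
  if (any(pureM)) {
    i <- cov[pureM]
    op[pureM] <- "M"
    base[pureM] <- substr(reads$seq[i], pos - reads$ref_start[i] + 1L,
                          pos - reads$ref_start[i] + 1L)
  }
  for (j in which(!pureM)) {
    hit <- read_base_at(reads$ref_start[cov[j]], parsed[[cov[j]]],
                        reads$seq[cov[j]], pos)
    op[j] <- hit$op
    base[j] <- hit$base
  }
  data.frame(idx = cov, op = op, base = base, stringsAsFactors = FALSE)
}

## Insertion events of one read: data frame (anchor, seq) with the anchor at
## the reference position of the base immediately preceding the inserted
## sequence (0-based). Leading S/I never reach here (cleaned at simulation).
read_insertions <- function(ref_start, parsed, seq) {
  rp <- ref_start
  qp <- 0L
  anchors <- integer(0)
  seqs <- character(0)
  for (k in seq_along(parsed$op)) {
    op <- parsed$op[k]
    len <- parsed$len[k]
    if (op == "M") {
      rp <- rp + len
      qp <- qp + len
    } else if (op == "D") {
      rp <- rp + len
    } else if (op == "I") {
      anchors <- c(anchors, rp - 1L)
      seqs <- c(seqs, substr(seq, qp + 1L, qp + len))
      qp <- qp + len
    } else {
      qp <- qp + len
    }
  }
  data.frame(anchor = anchors, seq = seqs, stringsAsFactors = FALSE)
}
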