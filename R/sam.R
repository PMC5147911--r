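## Minimal SAM text IO for the simulator's alignments.
##
## The pipeline passes reads around as data frames; SAM is the on-disk
## interchange format. Truth labels travel in optional tags (XC contributor,
## XP platform) so a written file round-trips losslessly.

sam_flags <- function(reads) {
  flag <- integer(nrow(reads))
  paired <- !is.na(reads$mate)
  flag[paired] <- flag[paired] + 1L + 2L +
    ifelse(reads$mate[paired] == 1L, 64L, 128L)
  flag <- flag + ifelse(reads$strand == "-", 16L, 0L)
  if (any(paired)) {
    ## mate strand: locate the other mate of each pair
    key <- paste(reads$pair_id, 3L - reads$mate)
    mstrand <- reads$strand[match(key, paste(reads$pair_id, reads$mate))]
    add <- paired & !is.na(mstrand) & mstrand == "-"
    flag[add] <- flag[add] + 32L
  }
  flag + ifelse(reads$secondary, 256L, 0L) + ifelse(!reads$mapped, 4L, 0L)
}

#' Write reads as a SAM file
#'
#' Emits a valid header (`@HD`, `@SQ`) and one alignment line per read, with
#' proper-pair flags for paired short reads and truth labels in `XC`/`XP`
#' tags. Output is deterministic in input order.
#'
#' @param reads read data frame.
#' @param ref the reference genome.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", ref$name, "\tLN:", ref$length))
  if (nrow(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- sam_flags(reads)
  paired <- !is.na(reads$mate)
  rnext <- ifelse(paired, "=", "*")
  mate_key <- paste(reads$pair_id, 3L - reads$mate)
  midx <- match(mate_key, paste(reads$pair_id, reads$mate))
  pnext <- ifelse(paired & !is.na(midx), reads$ref_start[midx] + 1L, 0L)
  parsed <- parse_cigar(reads$cigar)
  span <- cigar_ref_span(parsed)
  tlen <- rep(0L, nrow(reads))
  if (any(paired)) {
    lo <- pmin(reads$ref_start, reads$ref_start[midx])
    hi <- pmax(reads$ref_start + span, reads$ref_start[midx] + span[midx])
    t <- hi - lo
    tlen[paired] <- ifelse(reads$ref_start[paired] <= reads$ref_start[midx[paired]],
                           t[paired], -t[paired])
  }
  qname <- ifelse(paired, reads$pair_id, reads$read_id)
  lines <- paste(qname, flag, ref$name, reads$ref_start + 1L, 60L,
                 reads$cigar, rnext, pnext, tlen, reads$seq, reads$qual,
                 paste0("XC:Z:", reads$contributor),
                 paste0("XP:Z:", reads$platform), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file written by [write_sam()]
#'
#' @param path SAM file.
#' @return Read data frame in the package's internal layout.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_reads())
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  paired <- bitwAnd(flag, 1L) > 0L
  mate <- ifelse(paired, ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L), NA_integer_)
  qname <- get(1)
  tag <- function(prefix) {
    vapply(f, function(x) {
      hit <- x[startsWith(x, prefix)]
      if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
    }, character(1))
  }
  df <- data.frame(
    read_id = ifelse(paired, paste0(qname, "/", mate), qname),
    contributor = tag("XC:Z:"),
    platform = tag("XP:Z:"),
    ref_start = as.integer(get(4)) - 1L,
    cigar = get(6),
    seq = get(10),
    qual = get(11),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    pair_id = ifelse(paired, qname, NA_character_),
    mate = mate,
    secondary = bitwAnd(flag, 256L) > 0L,
    mapped = bitwAnd(flag, 4L) == 0L,
    stringsAsFactors = FALSE)
  df
}
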