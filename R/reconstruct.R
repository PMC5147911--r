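## Reference-guided consensus reconstruction and assembly statistics.
##
## The phased long-read pool and the deconvolved short-read set of one
## contributor are merged into a single pileup; every alternate signal (SNP,
## normalised insertion, deletion) reaching the reconstruction VAF (0.75 by
## default) is applied to the reference to produce the contributor
## consensus. Uncovered reference positions are N-filled and reported as
## gaps. Nx/NGAx curves operate on any contig/block length list.

#' Reconstruct one contributor's consensus
#'
#' @param phased_long long-read data frame (the contributor's phased pool).
#' @param deconvolved_short short-read data frame (private + shared pairs).
#' @param ref the reference genome.
#' @param vaf reconstruction VAF threshold (default 0.75).
#' @param min_depth depth floor for calling (positions below it contribute
#'   the reference base).
#' @param truth optional truth variant data frame (`pos`, `ref`, `alt`) to
#'   classify the supporting call set against.
#' @param contributor_id label for reporting.
#' @return A `mito_consensus`: `sequence`, `calls` (supporting SNP/INS/DEL
#'   calls at the threshold), `gaps` (0-based uncovered positions),
#'   `concordance` (a [classify()] result against `truth`, or NULL), and
#'   `contig_lengths` (consensus split at N gaps).
#' @export
reconstruct_contributor <- function(phased_long, deconvolved_short, ref,
                                    vaf = 0.75, min_depth = 20L,
                                    truth = NULL, contributor_id = "") {
  pool <- rbind(phased_long, deconvolved_short)
  if (nrow(pool) == 0) stop("empty read pool")
  pile <- build_pileup(pool, ref)
  calls <- call_variants(pile, ref, threshold = vaf, min_depth = min_depth,
                         ploidy_mode = "single_source", include_indels = TRUE)
  if (nrow(calls)) {
    ## per-base DEL calls are re-anchored VCF-style (anchor base precedes
    ## the deleted base) before normalisation
    isdel <- calls$vclass == "DEL" & calls$pos > 0L
    calls <- calls[calls$vclass != "DEL" | calls$pos > 0L, , drop = FALSE]
    isdel <- calls$vclass == "DEL"
    anchor <- substr(ref$sequence, calls$pos, calls$pos)  # 0-based pos-1
    norm <- left_align_and_decompose(
      data.frame(pos = ifelse(isdel, calls$pos - 1L, calls$pos),
                 ref = ifelse(isdel, paste0(anchor, calls$ref), calls$ref),
                 alt = ifelse(isdel, anchor, calls$alt),
                 stringsAsFactors = FALSE), ref)
  } else {
    norm <- calls[, c("pos", "ref", "alt", "vclass")]
    norm$vclass <- character(0)
  }

  chars <- ref_chars(ref)
  gaps <- which(pile$depth == 0L) - 1L
  out <- as.list(chars)
  if (length(gaps)) for (g in gaps) out[[g + 1L]] <- "N"
  if (nrow(norm)) {
    for (i in seq_len(nrow(norm))) {
      p <- norm$pos[i]
      if (norm$vclass[i] == "SNP") {
        if (length(out[[p + 1L]]) && out[[p + 1L]][1] != "N")
          out[[p + 1L]][1] <- norm$alt[i]
      } else if (norm$vclass[i] == "INS") {
        out[[p + 1L]] <- c(out[[p + 1L]][1], strsplit(
          substr(norm$alt[i], 2L, nchar(norm$alt[i])), "")[[1]])
      } else if (norm$vclass[i] == "DEL") {
        ndel <- nchar(norm$ref[i]) - 1L
        for (d in seq_len(ndel))
          if (p + d < ref$length) out[[p + d + 1L]] <- character(0)
      }
    }
  }
  consensus <- paste(unlist(out), collapse = "")
  contigs <- nchar(strsplit(gsub("N+", "N", consensus), "N")[[1]])
  contigs <- sort(contigs[contigs > 0], decreasing = TRUE)

  concordance <- NULL
  if (!is.null(truth)) {
    truth_norm <- left_align_and_decompose(truth, ref)
    concordance <- classify(norm, truth_norm)
  }
  structure(list(contributor_id = contributor_id, sequence = consensus,
                 calls = norm, gaps = gaps, concordance = concordance,
                 contig_lengths = contigs, pileup_depth = pile$depth),
            class = "mito_consensus")
}

#' @export
print.mito_consensus <- function(x, ...) {
  cat("mito_consensus '", x$contributor_id, "': ", nchar(x$sequence),
      " bp, ", nrow(x$calls), " supporting call(s), ", length(x$gaps),
      " gap position(s)\n", sep = "")
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Nx curve of a contig length set
#'
#' Nx is the length of the smallest contig in the minimal prefix of the
#' descending length list whose sum reaches x% of the total assembly
#' length, computed for integer x in 1..100. N50 is the curve at x = 50.
#'
#' @param contig_lengths positive contig lengths.
#' @return A `mito_assembly_stats` list: `contig_lengths` (descending),
#'   `total`, `nx` (named numeric over 1..100), `n50`.
#' @export
nx_curve <- function(contig_lengths) {
  if (!length(contig_lengths) || any(contig_lengths <= 0))
    stop("contig lengths must be a non-empty positive vector")
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  cs <- cumsum(lens)
  total <- cs[length(cs)]
  nx <- vapply(1:100, function(x) lens[which(cs >= x / 100 * total)[1]],
               numeric(1))
  structure(list(contig_lengths = lens, total = total,
                 nx = setNames(nx, 1:100), n50 = nx[50]),
            class = "mito_assembly_stats")
}

#' NGAx curve of aligned block lengths against a genome size
#'
#' As [nx_curve()], but thresholds are x% of `genome_size` and the inputs
#' are alignment-broken block lengths; NA (undefined) for x where the
#' cumulative blocks fall short of x% of the genome.
#'
#' @param aligned_blocks positive block lengths.
#' @param genome_size reference genome size in bp.
#' @return A `mito_assembly_stats` list with `ngax` and `nga50`.
#' @export
ngax_curve <- function(aligned_blocks, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (!length(aligned_blocks) || any(aligned_blocks <= 0))
    stop("block lengths must be a non-empty positive vector")
  lens <- sort(as.numeric(aligned_blocks), decreasing = TRUE)
  cs <- cumsum(lens)
  ngax <- vapply(1:100, function(x) {
    i <- which(cs >= x / 100 * genome_size)[1]
    if (is.na(i)) NA_real_ else lens[i]
  }, numeric(1))
  structure(list(contig_lengths = lens, total = cs[length(cs)],
                 genome_size = genome_size,
                 ngax = setNames(ngax, 1:100), nga50 = ngax[50]),
            class = "mito_assembly_stats")
}

#' Per-base coverage track
#'
#' Depth counts reads whose M/D reference spans cover each base (identical
#' to pileup depth). Also returns summary statistics and a BED-graph table.
#'
#' @param reads read data frame.
#' @param ref the reference genome.
#' @return List with `depth` (length-L integer), `summary` (mean, median,
#'   quartiles), and `bedgraph` data frame (chrom, start, end, depth;
#'   0-based half-open).
#' @export
coverage_track <- function(reads, ref) {
  L <- ref$length
  if (nrow(reads)) {
    parsed <- parse_cigar(reads$cigar)
    span <- cigar_ref_span(parsed)
    keep <- reads$mapped & !reads$secondary
    cov <- IRanges::coverage(IRanges::IRanges(start = reads$ref_start[keep] + 1L,
                                              width = span[keep]), width = L)
    depth <- as.integer(cov)
  } else {
    depth <- integer(L)
  }
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  bed <- data.frame(chrom = ref$name, start = c(0L, head(ends, -1L)),
                    end = ends, depth = r$values, stringsAsFactors = FALSE)
  list(depth = depth,
       summary = c(mean = mean(depth), median = median(depth),
                   q25 = unname(quantile(depth, 0.25)),
                   q75 = unname(quantile(depth, 0.75))),
       bedgraph = bed)
}

#' Write a consensus as FASTA
#' @param consensus a `mito_consensus`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  nm <- paste0("consensus_", consensus$contributor_id)
  x <- Biostrings::DNAStringSet(setNames(consensus$sequence, nm))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
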