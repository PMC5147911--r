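## Per-position allele counting and VAF-threshold SNP calling.
##
## The variant allele frequency of an allele at a site is the fraction of
## all reads covering the site that carry that allele; the denominator
## includes mismatching "other" bases and reads deleted at the site, which
## matches how count/percentage tables for mixtures are reported.

#' Build a pileup from aligned reads
#'
#' M ops contribute base counts at their consumed reference positions, D ops
#' increment a per-position deletion count, I ops record an insertion event
#' anchored at the reference base immediately preceding the inserted
#' sequence, S ops contribute nothing. Secondary and unmapped reads are
#' excluded. Depth at a position is base counts plus deletions, i.e. the
#' number of covering reads.
#'
#' @param reads read data frame.
#' @param ref the reference genome.
#' @return A `mito_pileup`: list with `counts` (4 x L integer matrix, rows
#'   A/C/G/T), `del` (length-L deletions), `depth`, `ins` (data frame
#'   `pos`/`seq`/`count` of insertion events), and `ref`.
#' @export
build_pileup <- function(reads, ref) {
  reads <- reads[reads$mapped & !reads$secondary, , drop = FALSE]
  L <- ref$length
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  del <- integer(L)
  ins <- data.frame(pos = integer(0), seq = character(0), count = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(reads) > 0) {
    validate_reads(reads, ref)
    parsed <- parse_cigar(reads$cigar)
    nops <- vapply(parsed, function(p) length(p$op), integer(1))
    ridx <- rep.int(seq_len(nrow(reads)), nops)
    op <- unlist(lapply(parsed, `[[`, "op"))
    len <- unlist(lapply(parsed, `[[`, "len"))
    ## per-op query/reference offsets within each read
    qconsume <- ifelse(op %in% CIGAR_QUERY_OPS, len, 0L)
    rconsume <- ifelse(op %in% CIGAR_REF_OPS, len, 0L)
    first_op <- rep.int(cumsum(nops) - nops + 1L, nops)
    before_q <- cumsum(qconsume) - qconsume
    before_r <- cumsum(rconsume) - rconsume
    qoff <- before_q - before_q[first_op]
    roff <- before_r - before_r[first_op]
    shift <- reads$ref_start[ridx] + roff

    isM <- op == "M"
    if (any(isM)) {
      pieces <- substring(reads$seq[ridx[isM]], qoff[isM] + 1L,
                          qoff[isM] + len[isM])
      cm <- Biostrings::consensusMatrix(
        Biostrings::DNAStringSet(pieces), shift = shift[isM], width = L)
      counts <- matrix(as.integer(cm[DNA_BASES, , drop = FALSE]), nrow = 4L,
                       dimnames = list(DNA_BASES, NULL))
    }
    isD <- op == "D"
    if (any(isD)) {
      cov <- IRanges::coverage(IRanges::IRanges(start = shift[isD] + 1L,
                                                width = len[isD]), width = L)
      del <- as.integer(cov)
    }
    isI <- op == "I"
    if (any(isI)) {
      anchors <- shift[isI] - 1L
      seqs <- substring(reads$seq[ridx[isI]], qoff[isI] + 1L,
                        qoff[isI] + len[isI])
      tab <- aggregate(list(count = rep(1L, sum(isI))),
                       by = list(pos = anchors, seq = seqs), FUN = sum)
      ins <- tab[order(tab$pos), , drop = FALSE]
      rownames(ins) <- NULL
    }
  }
  structure(list(counts = counts, del = del,
                 depth = as.integer(colSums(counts)) + del,
                 ins = ins, ref_name = ref$name, length = L),
            class = "mito_pileup")
}

#' Extract one pileup column
#' @param pileup a `mito_pileup`.
#' @param pos 0-based position.
#' @return List with `pos`, `counts` (named A/C/G/T), `deletion_count`,
#'   `insertion_events`, `depth`.
#' @export
pileup_column <- function(pileup, pos) {
  stopifnot(pos >= 0, pos < pileup$length)
  ins <- pileup$ins[pileup$ins$pos == pos, c("seq", "count"), drop = FALSE]
  list(pos = pos, counts = setNames(pileup$counts[, pos + 1L], DNA_BASES),
       deletion_count = pileup$del[pos + 1L],
       insertion_events = ins, depth = pileup$depth[pos + 1L])
}

#' Variant allele frequency of an allele in a pileup column
#'
#' The denominator is the column depth: every read covering the position,
#' including those carrying other bases or a deletion.
#'
#' @param column a [pileup_column()] (or any list with `counts` and `depth`).
#' @param allele one of A/C/G/T.
#' @return Proportion in `[0, 1]`.
#' @export
vaf <- function(column, allele) {
  stopifnot(allele %in% DNA_BASES)
  if (column$depth == 0)
    stop("VAF undefined at depth 0 (position ", column$pos, ")")
  unname(column$counts[allele]) / column$depth
}

## Internal caller covering SNPs and (optionally) indel signals; used by
## call_snps (SNP-only surface) and by consensus reconstruction.
call_variants <- function(pileup, ref, threshold, min_depth = 20L,
                          ploidy_mode = c("single_source", "mixture"),
                          include_indels = FALSE) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(threshold > 0, threshold <= 1)
  chars <- ref_chars(ref)
  depth <- pileup$depth
  ok <- depth >= pmax(min_depth, 1L)
  calls <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      vaf = numeric(0), depth = integer(0),
                      vclass = character(0), stringsAsFactors = FALSE)
  if (any(ok)) {
    vafm <- sweep(pileup$counts[, ok, drop = FALSE], 2L, depth[ok], "/")
    refrow <- match(chars[ok], DNA_BASES)
    vafm[cbind(refrow, seq_len(ncol(vafm)))] <- -1  # never call the ref base
    hits <- which(vafm >= threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      pos0 <- which(ok)[hits[, 2L]] - 1L
      calls <- data.frame(pos = pos0, ref = chars[pos0 + 1L],
                          alt = DNA_BASES[hits[, 1L]],
                          vaf = vafm[hits], depth = depth[pos0 + 1L],
                          vclass = "SNP", stringsAsFactors = FALSE)
      keep_n <- if (ploidy_mode == "single_source") 1L else 2L
      calls <- calls[order(calls$pos, -calls$vaf), , drop = FALSE]
      calls <- do.call(rbind, lapply(split(calls, calls$pos),
                                     function(d) head(d, keep_n)))
    }
  }
  if (include_indels) {
    ins <- pileup$ins
    if (nrow(ins)) {
      d <- depth[ins$pos + 1L]
      keep <- d >= pmax(min_depth, 1L) & ins$count / pmax(d, 1L) >= threshold
      if (any(keep)) {
        i <- ins[keep, , drop = FALSE]
        calls <- rbind(calls, data.frame(
          pos = i$pos, ref = chars[i$pos + 1L],
          alt = paste0(chars[i$pos + 1L], i$seq),
          vaf = i$count / d[keep], depth = d[keep], vclass = "INS",
          stringsAsFactors = FALSE))
      }
    }
    dvaf <- pileup$del / pmax(depth, 1L)
    dkeep <- which(ok & dvaf >= threshold)
    if (length(dkeep)) {
      pos0 <- dkeep - 1L
      calls <- rbind(calls, data.frame(
        pos = pos0, ref = chars[pos0 + 1L], alt = "-", vaf = dvaf[dkeep],
        depth = depth[dkeep], vclass = "DEL", stringsAsFactors = FALSE))
    }
  }
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call SNPs at a VAF threshold
#'
#' Every non-reference base whose VAF reaches `threshold` at a position with
#' at least `min_depth` covering reads yields a SNP call. Insertion and
#' deletion signals are never emitted (SNP-only filter). In
#' `single_source` mode only the highest-VAF alternate is kept per position;
#' in `mixture` mode up to two alternates may be kept. The depth floor
#' replaces a caller quality filter: the long-read platform's quality scores
#' are not phred-scaled, so covering-read count is the transparent analogue.
#'
#' @param pileup a `mito_pileup`.
#' @param ref the reference genome.
#' @param threshold VAF threshold in (0, 1].
#' @param min_depth minimum covering reads per called position.
#' @param ploidy_mode `"single_source"` or `"mixture"`.
#' @return A `mito_calls` data frame (`pos`, `ref`, `alt`, `vaf`, `depth`,
#'   `vclass`) with the threshold and mode stored as attributes.
#' @export
call_snps <- function(pileup, ref, threshold, min_depth = 20L,
                      ploidy_mode = c("single_source", "mixture")) {
  ploidy_mode <- match.arg(ploidy_mode)
  calls <- call_variants(pileup, ref, threshold, min_depth, ploidy_mode,
                         include_indels = FALSE)
  structure(calls, threshold = threshold, ploidy_mode = ploidy_mode,
            class = c("mito_calls", "data.frame"))
}

#' Left-align and decompose variants
#'
#' Normalises a variant table: multi-allelic records (comma-separated ALT)
#' are split into biallelic records; same-length block substitutions are
#' decomposed into per-position SNPs at the positions that differ; insertions
#' and deletions are shifted left while flanked by repeated sequence. Output
#' is sorted by position and the operation is idempotent.
#'
#' @param variants data frame with 0-based `pos`, `ref`, `alt` (and
#'   optionally `vclass`; it is recomputed).
#' @param ref the reference genome.
#' @return Normalised variant data frame (`pos`, `ref`, `alt`, `vclass`).
#' @export
left_align_and_decompose <- function(variants, ref) {
  chars <- ref_chars(ref)
  out <- list()
  emit <- function(pos, refa, alta) {
    out[[length(out) + 1L]] <<- data.frame(pos = pos, ref = refa, alt = alta,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    refa <- variants$ref[i]
    for (alta in strsplit(variants$alt[i], ",", fixed = TRUE)[[1]]) {
      rl <- nchar(refa); al <- nchar(alta)
      check <- substr(ref$sequence, pos + 1L, pos + rl)
      if (check != refa)
        stop("reference allele mismatch at position ", pos, ": variant says ",
             refa, ", reference has ", check)
      if (rl == al) {
        rb <- strsplit(refa, "")[[1]]; ab <- strsplit(alta, "")[[1]]
        diff <- which(rb != ab)
        for (d in diff) emit(pos + d - 1L, rb[d], ab[d])
      } else if (rl < al && substr(alta, 1L, rl) == refa && rl == 1L) {
        ## insertion: anchor base + inserted sequence
        s <- strsplit(substr(alta, 2L, al), "")[[1]]
        p <- pos
        while (p > 0L && chars[p + 1L] == s[length(s)]) {
          s <- c(s[length(s)], s[-length(s)])
          p <- p - 1L
        }
        emit(p, chars[p + 1L], paste0(chars[p + 1L], paste(s, collapse = "")))
      } else if (rl > al && substr(refa, 1L, al) == alta && al == 1L) {
        ## deletion: anchor base + deleted sequence
        s <- strsplit(substr(refa, 2L, rl), "")[[1]]
        p <- pos
        while (p > 0L && chars[p + 1L] == s[length(s)]) {
          s <- c(s[length(s)], s[-length(s)])
          p <- p - 1L
        }
        emit(p, paste0(chars[p + 1L], paste(s, collapse = "")), chars[p + 1L])
      } else {
        ## complex allele: strip shared prefix then re-dispatch once
        k <- 0L
        while (k < min(rl, al) - 1L &&
               substr(refa, k + 1L, k + 1L) == substr(alta, k + 1L, k + 1L))
          k <- k + 1L
        if (k > 0L) {
          sub <- left_align_and_decompose(
            data.frame(pos = pos + k, ref = substr(refa, k + 1L, rl),
                       alt = substr(alta, k + 1L, al),
                       stringsAsFactors = FALSE), ref)
          for (j in seq_len(nrow(sub))) emit(sub$pos[j], sub$ref[j], sub$alt[j])
        } else {
          emit(pos, refa, alta)  # irreducible; kept as-is
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      vclass = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$vclass <- ifelse(nchar(res$ref) == 1L & nchar(res$alt) == 1L, "SNP",
                       ifelse(nchar(res$ref) < nchar(res$alt), "INS", "DEL"))
  res <- res[!duplicated(paste(res$pos, res$ref, res$alt)), , drop = FALSE]
  res <- res[order(res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write per-base depth as a BED-graph
#' @param depth integer depth vector over `[0, L)`.
#' @param ref the reference genome.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(depth, ref, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  write.table(data.frame(ref$name, starts, ends, r$values),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write calls in the VCF-like tab format
#' @param calls a calls data frame.
#' @param ref the reference genome.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, ref, path) {
  n <- nrow(calls)
  out <- data.frame(CHROM = rep_len(ref$name, n), POS = calls$pos + 1L,
                    REF = calls$ref, ALT = calls$alt, CLASS = calls$vclass,
                    VAF = if (is.null(calls$vaf)) rep(NA_real_, n)
                          else round_metric(calls$vaf),
                    DEPTH = if (is.null(calls$depth)) rep(NA_integer_, n)
                            else calls$depth,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
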