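## Phasing of amplicon-spanning long reads.
##
## Reads that intersect an interval and exceed a query-length floor (8000
## bases by default, so only fully extended amplicon molecules qualify) are
## partitioned into two contributor pools by majority vote of their observed
## alleles at known heterozygous sites, followed by consensus-refinement
## passes. Missing observations (site under a deletion or clip) are excluded
## from the vote rather than counted as mismatches.

#' Extract amplicon-spanning reads
#'
#' Membership in a set requires the read's reference span to intersect the
#' interval (0-based half-open) AND its query length to exceed
#' `min_query_len`.
#'
#' @param reads read data frame.
#' @param intervals list of `c(start, end)` 0-based half-open intervals.
#' @param min_query_len query-length floor in bases (strict inequality).
#' @return List of `mito_spanning` sets, one per interval, each with
#'   `interval` and `reads`.
#' @export
extract_spanning_reads <- function(reads,
                                   intervals = list(c(1000L, 8000L),
                                                    c(10000L, 15000L)),
                                   min_query_len = 8000L) {
  if (min_query_len <= 0) stop_config("min_query_len must be positive")
  if (nrow(reads)) {
    parsed <- parse_cigar(reads$cigar)
    span <- cigar_ref_span(parsed)
    qlen <- nchar(reads$seq)
  }
  lapply(intervals, function(iv) {
    keep <- if (nrow(reads) == 0) logical(0) else
      (reads$ref_start < iv[2] & reads$ref_start + span > iv[1] &
         qlen > min_query_len)
    structure(list(interval = iv, reads = reads[keep, , drop = FALSE]),
              class = "mito_spanning")
  })
}

## observed allele matrix: reads x sites, NA where missing / non-M
allele_matrix <- function(reads, sites) {
  m <- matrix(NA_character_, nrow(reads), length(sites))
  for (j in seq_along(sites)) {
    hits <- bases_at_position(reads, sites[j])
    hit_m <- hits[hits$op == "M" & !is.na(hits$op), , drop = FALSE]
    m[hit_m$idx, j] <- hit_m$base
  }
  m
}

#' Partition spanning reads into two haplotype pools
#'
#' Each read's observed base at every covered het site (via CIGAR walk;
#' deletions and clips give missing values) is compared against the two
#' candidate allele vectors. A read joins the pool whose candidate it
#' matches at strictly more covered sites; exact ties or zero covered sites
#' leave it unassigned. Each refinement pass recomputes the pools' majority
#' consensus allele per site and re-assigns, until convergence or
#' `max_iters`. Deterministic given input order.
#'
#' @param spanning a `mito_spanning` set from [extract_spanning_reads()].
#' @param het_sites data frame with 0-based `pos`, `allele_A`, `allele_B`.
#' @param max_iters maximum refinement passes.
#' @return A `mito_partition`: `pool_A`, `pool_B`, `unassigned` read data
#'   frames, the per-site consensus vectors, and `site_report` (filled by
#'   [pool_allele_report()]).
#' @export
phase_reads <- function(spanning, het_sites, max_iters = 5L) {
  iv <- spanning$interval
  sites <- het_sites[het_sites$pos >= iv[1] & het_sites$pos < iv[2], ,
                     drop = FALSE]
  if (nrow(sites) == 0)
    stop("phasing impossible: no heterozygous sites inside [",
         iv[1], ", ", iv[2], ")")
  if (any(sites$allele_A == sites$allele_B))
    stop("het site with identical alleles")
  reads <- spanning$reads
  obs <- allele_matrix(reads, sites$pos)

  cand_A <- sites$allele_A
  cand_B <- sites$allele_B
  assign_by <- function(cA, cB) {
    score_A <- rowSums(obs == matrix(cA, nrow(reads), length(cA), byrow = TRUE),
                       na.rm = TRUE)
    score_B <- rowSums(obs == matrix(cB, nrow(reads), length(cB), byrow = TRUE),
                       na.rm = TRUE)
    ifelse(score_A > score_B, "A", ifelse(score_B > score_A, "B", "U"))
  }
  lab <- assign_by(cand_A, cand_B)
  for (it in seq_len(max_iters)) {
    consensus <- function(which_pool, fallback) {
      rows <- which(lab == which_pool)
      vapply(seq_along(fallback), function(j) {
        x <- obs[rows, j]
        x <- x[!is.na(x)]
        if (!length(x)) return(fallback[j])
        tab <- sort(table(x), decreasing = TRUE)
        ## deterministic, label-symmetric tie-break: keep the pool's own
        ## candidate allele when it ties for the majority
        top <- names(tab)[tab == max(tab)]
        if (fallback[j] %in% top) fallback[j] else top[1]
      }, character(1))
    }
    new_A <- consensus("A", cand_A)
    new_B <- consensus("B", cand_B)
    new_lab <- assign_by(new_A, new_B)
    if (identical(new_lab, lab) && identical(new_A, cand_A) &&
        identical(new_B, cand_B)) break
    lab <- new_lab; cand_A <- new_A; cand_B <- new_B
  }
  part <- structure(list(
    pool_A = reads[lab == "A", , drop = FALSE],
    pool_B = reads[lab == "B", , drop = FALSE],
    unassigned = reads[lab == "U", , drop = FALSE],
    sites = sites, consensus_A = cand_A, consensus_B = cand_B,
    interval = iv, site_report = NULL), class = "mito_partition")
  part$site_report <- pool_allele_report(part, sites$pos)
  part
}

#' @export
print.mito_partition <- function(x, ...) {
  cat("mito_partition over [", x$interval[1], ", ", x$interval[2], "): ",
      nrow(x$pool_A), " in pool A, ", nrow(x$pool_B), " in pool B, ",
      nrow(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

#' Per-site allele counts within each phased pool
#'
#' For each site and pool, counts of the two tracked alleles plus "Other"
#' (any other base, or a deletion at the site), with percentages of the
#' pool's depth at the site rounded to whole percent. Sites uncovered in a
#' pool are flagged with depth 0.
#'
#' @param partition a `mito_partition`.
#' @param sites 0-based positions (defaults to the partition's het sites).
#' @return Data frame: pool, pos, tracked allele counts, other, depth and
#'   whole-number percentages.
#' @export
pool_allele_report <- function(partition, sites = partition$sites$pos) {
  site_tab <- partition$sites[match(sites, partition$sites$pos), , drop = FALSE]
  rows <- list()
  for (pool in c("A", "B")) {
    reads <- if (pool == "A") partition$pool_A else partition$pool_B
    for (j in seq_along(sites)) {
      aA <- site_tab$allele_A[j]; aB <- site_tab$allele_B[j]
      if (nrow(reads)) {
        hits <- bases_at_position(reads, sites[j])
        depth <- nrow(hits)
        nA <- sum(hits$op == "M" & hits$base == aA, na.rm = TRUE)
        nB <- sum(hits$op == "M" & hits$base == aB, na.rm = TRUE)
      } else {
        depth <- nA <- nB <- 0L
      }
      other <- depth - nA - nB
      rows[[length(rows) + 1L]] <- data.frame(
        pool = pool, pos = sites[j], allele_A = aA, allele_B = aB,
        count_A = nA, count_B = nB, other = other, depth = depth,
        pct_A = if (depth > 0) as_percent(nA / depth) else NA_integer_,
        pct_B = if (depth > 0) as_percent(nB / depth) else NA_integer_,
        pct_other = if (depth > 0) as_percent(other / depth) else NA_integer_,
        uncovered = depth == 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
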