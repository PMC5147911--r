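## Deconvolution of short read pairs from a mixture using private variants.
##
## Each read pair is evaluated at every panel site it covers. At a private
## SNP the base under the alignment is evidence only when the covering CIGAR
## op is a match (M) and the base equals one of the two contributor alleles;
## at a private insertion a mate is eligible only when its span covers both
## flanks 10 bp around the insertion anchor, in which case the presence (or
## absence) of an I op at the anchor attributes it to the carrier (or the
## other contributor). Verdicts from both mates are pooled and resolved by
## majority; ties and pairs without evidence stay in the shared pool.

#' Build a private-variant panel from a combined truth set
#'
#' SNP rows carry the allele of each contributor (the non-carrier holds the
#' reference base); insertion rows carry the inserted sequence and the
#' carrier label.
#'
#' @param truthset a [combine_truth_sets()] result, or any data frame with
#'   `pos`, `ref`, `alt`, `vclass`, `sharing`.
#' @param labels the two contributor labels used in `sharing`.
#' @return A `mito_panel` list with data frames `snps`
#'   (`pos`, `allele_A`, `allele_B`) and `insertions` (`pos`, `seq`,
#'   `carrier`).
#' @export
private_variant_panel <- function(truthset, labels = c("A", "B")) {
  priv <- truthset[truthset$sharing != "shared", , drop = FALSE]
  snp <- priv[priv$vclass == "SNP", , drop = FALSE]
  isA <- snp$sharing == paste0("private:", labels[1])
  snps <- data.frame(pos = snp$pos,
                     allele_A = ifelse(isA, snp$alt, snp$ref),
                     allele_B = ifelse(isA, snp$ref, snp$alt),
                     stringsAsFactors = FALSE)
  ins <- priv[priv$vclass == "INS", , drop = FALSE]
  insertions <- data.frame(
    pos = ins$pos,
    seq = substr(ins$alt, 2L, nchar(ins$alt)),
    carrier = ifelse(ins$sharing == paste0("private:", labels[1]),
                     labels[1], labels[2]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(c(snps$pos, insertions$pos)))
    stop_config("panel positions must be unique")
  if (nrow(snps) && any(snps$allele_A == snps$allele_B))
    stop_config("panel SNP with identical alleles")
  structure(list(snps = snps, insertions = insertions, labels = labels),
            class = "mito_panel")
}

#' SNP verdict for one read pair at one site
#'
#' @param pair data frame of the pair's mates.
#' @param site list/row with `pos`, `allele_A`, `allele_B`.
#' @return `"A"`, `"B"` or `"no_evidence"` (per covering mate the base must
#'   sit under an M op and equal one of the two alleles). With both mates
#'   covering, the first informative mate decides; disagreeing mates give
#'   `"no_evidence"`.
#' @export
assign_pair_by_snp <- function(pair, site) {
  hits <- bases_at_position(pair, site$pos)
  if (!nrow(hits)) stop("neither mate covers position ", site$pos)
  v <- character(0)
  for (i in seq_len(nrow(hits))) {
    if (is.na(hits$op[i]) || hits$op[i] != "M") next
    if (hits$base[i] == site$allele_A) v <- c(v, "A")
    else if (hits$base[i] == site$allele_B) v <- c(v, "B")
  }
  v <- unique(v)
  if (length(v) == 1L) v else "no_evidence"
}

#' Insertion verdict for one read pair
#'
#' A mate is eligible when its reference span covers both `pos - 10` and
#' `pos + 10`; an eligible mate with an I op anchored at `pos` attributes
#' the pair to the carrier, an eligible mate without one to the other
#' contributor.
#'
#' @param pair data frame of the pair's mates.
#' @param ins list/row with `pos`, `seq`, `carrier`; `other` is the opposing
#'   label.
#' @param other label of the non-carrier.
#' @return The carrier label, the other label, or `"no_evidence"`.
#' @export
assign_pair_by_insertion <- function(pair, ins, other) {
  parsed <- parse_cigar(pair$cigar)
  span <- cigar_ref_span(parsed)
  eligible <- pair$ref_start <= ins$pos - 10L &
    pair$ref_start + span > ins$pos + 10L
  if (!any(eligible)) return("no_evidence")
  v <- character(0)
  for (i in which(eligible)) {
    evts <- read_insertions(pair$ref_start[i], parsed[[i]], pair$seq[i])
    v <- c(v, if (any(evts$anchor == ins$pos)) ins$carrier else other)
  }
  v <- unique(v)
  if (length(v) == 1L) v else "no_evidence"
}

#' Deconvolve mixture read pairs into contributor pools
#'
#' Evaluates every pair at every panel site it covers, aggregates the
#' verdicts by majority, and partitions pairs into `pool_A`, `pool_B` and
#' `shared` (zero or tied evidence). Vectorised over sites; secondary
#' alignments are excluded from evidence but travel with their pair.
#'
#' @param reads short-read data frame from a mixture.
#' @param panel a [private_variant_panel()].
#' @return A `mito_assignment`: the three pools (data frames of whole
#'   pairs), and an `evidence` data frame (pair_id, pos, type, verdict).
#' @export
deconvolve <- function(reads, panel) {
  pair_ids <- unique(reads$pair_id[!is.na(reads$pair_id)])
  primary <- reads[!reads$secondary & !is.na(reads$pair_id), , drop = FALSE]
  n_sites <- nrow(panel$snps) + nrow(panel$insertions)
  if (n_sites == 0) {
    warning("empty panel: every pair is shared")
    return(structure(list(pool_A = reads[0, ], pool_B = reads[0, ],
                          shared = reads,
                          evidence = data.frame(pair_id = character(0),
                                                pos = integer(0),
                                                type = character(0),
                                                verdict = character(0))),
                     class = "mito_assignment"))
  }
  labels <- panel$labels
  ev <- list()

  ## SNP sites, vectorised across reads per site
  for (j in seq_len(nrow(panel$snps))) {
    s <- panel$snps[j, ]
    hits <- bases_at_position(primary, s$pos)
    hits <- hits[!is.na(hits$op) & hits$op == "M", , drop = FALSE]
    verdict <- ifelse(hits$base == s$allele_A, "A",
                      ifelse(hits$base == s$allele_B, "B", NA))
    keep <- !is.na(verdict)
    if (any(keep)) {
      ev[[length(ev) + 1L]] <- data.frame(
        pair_id = primary$pair_id[hits$idx[keep]], pos = s$pos, type = "SNP",
        verdict = verdict[keep], stringsAsFactors = FALSE)
    }
  }
  ## insertion sites: per-mate eligibility window
  if (nrow(panel$insertions)) {
    parsed <- parse_cigar(primary$cigar)
    span <- cigar_ref_span(parsed)
    has_ins <- vapply(parsed, function(p) any(p$op == "I"), logical(1))
    for (j in seq_len(nrow(panel$insertions))) {
      s <- panel$insertions[j, ]
      other <- setdiff(labels, s$carrier)
      eligible <- which(primary$ref_start <= s$pos - 10L &
                          primary$ref_start + span > s$pos + 10L)
      if (!length(eligible)) next
      carries <- logical(length(eligible))
      check <- eligible[has_ins[eligible]]
      for (i in seq_along(check)) {
        evts <- read_insertions(primary$ref_start[check[i]],
                                parsed[[check[i]]], primary$seq[check[i]])
        carries[match(check[i], eligible)] <- any(evts$anchor == s$pos)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        pair_id = primary$pair_id[eligible], pos = s$pos, type = "INS",
        verdict = ifelse(carries, ifelse(s$carrier == labels[1], "A", "B"),
                         ifelse(other == labels[1], "A", "B")),
        stringsAsFactors = FALSE)
    }
  }

  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pair_id = character(0), pos = integer(0), type = character(0),
               verdict = character(0), stringsAsFactors = FALSE)
  nA <- nB <- setNames(integer(length(pair_ids)), pair_ids)
  if (nrow(evidence)) {
    tA <- table(evidence$pair_id[evidence$verdict == "A"])
    tB <- table(evidence$pair_id[evidence$verdict == "B"])
    nA[names(tA)] <- as.integer(tA)
    nB[names(tB)] <- as.integer(tB)
  }
  lab <- ifelse(nA > nB, "A", ifelse(nB > nA, "B", "shared"))
  pool_of <- lab[match(reads$pair_id, pair_ids)]
  pool_of[is.na(pool_of)] <- "shared"
  structure(list(pool_A = reads[pool_of == "A", , drop = FALSE],
                 pool_B = reads[pool_of == "B", , drop = FALSE],
                 shared = reads[pool_of == "shared", , drop = FALSE],
                 evidence = evidence),
            class = "mito_assignment")
}

#' @export
print.mito_assignment <- function(x, ...) {
  cat("mito_assignment: ", length(unique(x$pool_A$pair_id)), " pairs private A, ",
      length(unique(x$pool_B$pair_id)), " private B, ",
      length(unique(x$shared$pair_id)), " shared\n", sep = "")
  invisible(x)
}

#' Build the two deconvolved read sets
#'
#' Adds each private pool back to the shared pool: `set_A = pool_A + shared`,
#' `set_B = pool_B + shared`.
#'
#' @param assignment a [deconvolve()] result.
#' @return List of two read data frames named `A` and `B`.
#' @export
build_deconvolved_sets <- function(assignment) {
  list(A = rbind(assignment$pool_A, assignment$shared),
       B = rbind(assignment$pool_B, assignment$shared))
}

#' Export a read set as a FASTQ pair
#'
#' Emits only proper pairs with both mates mapped and no secondary flag,
#' preserving mate order; reverse-strand mates are reverse-complemented back
#' to sequencing orientation. Orphaned mates are excluded and reported.
#'
#' @param reads read data frame.
#' @param r1_path,r2_path output FASTQ files for first and second mates.
#' @return Invisibly, a list with `n_pairs` and `orphans` (excluded ids).
#' @export
export_fastq <- function(reads, r1_path, r2_path) {
  ok <- reads[!is.na(reads$pair_id) & reads$mapped & !reads$secondary, ,
              drop = FALSE]
  cnt <- table(ok$pair_id)
  whole <- names(cnt)[cnt == 2L]
  orphans <- setdiff(unique(reads$pair_id[!is.na(reads$pair_id)]), whole)
  ok <- ok[ok$pair_id %in% whole, , drop = FALSE]
  ok <- ok[order(ok$pair_id, ok$mate), , drop = FALSE]
  write_one <- function(sub, path) {
    seqs <- ifelse(sub$strand == "-", revcomp(sub$seq), sub$seq)
    quals <- ifelse(sub$strand == "-",
                    vapply(sub$qual, function(q)
                      paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                      character(1)),
                    sub$qual)
    x <- Biostrings::DNAStringSet(setNames(seqs, sub$read_id))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(ok[ok$mate == 1L, , drop = FALSE], r1_path)
  write_one(ok[ok$mate == 2L, , drop = FALSE], r2_path)
  invisible(list(n_pairs = length(whole), orphans = orphans))
}
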