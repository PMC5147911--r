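## Dual-platform read simulation.
##
## Reads are emitted pre-aligned at their true positions: the haplotype
## carries its own base-level alignment to the reference (M for backbone
## bases, I for haplotype insertions) and injected sequencing errors extend
## that alignment (substitutions leave the CIGAR untouched; error insertions
## add I ops; deletions add D ops). No aligner runs anywhere in the
## pipeline, so alignment-induced artefacts are excluded by construction and
## every read keeps its contributor-of-origin truth label.

empty_reads <- function() {
  data.frame(read_id = character(0), contributor = character(0),
             platform = character(0), ref_start = integer(0),
             cigar = character(0), seq = character(0), qual = character(0),
             strand = character(0), pair_id = character(0), mate = integer(0),
             secondary = logical(0), mapped = logical(0),
             stringsAsFactors = FALSE)
}

## Inject per-base errors into one haplotype window and assemble the read.
## bvec: haplotype bases; rp: aligned 0-based reference position per base
## (NA for haplotype-insertion bases); hp: logical, base sits in an
## annotated homopolymer run. Returns list(seq, cigar, ref_start) or NULL
## when nothing alignable survives.
assemble_read <- function(bvec, rp, hp, profile) {
  n <- length(bvec)
  del_p <- profile$deletion
  if (profile$homopolymer_extra_deletion > 0 && any(hp))
    del_p <- del_p + profile$homopolymer_extra_deletion * hp
  kept <- if (any(del_p > 0)) runif(n) >= del_p else rep(TRUE, n)
  if (profile$substitution > 0) {
    subbed <- kept & (runif(n) < profile$substitution)
    if (any(subbed)) bvec[subbed] <- substitute_bases(bvec[subbed])
  }
  ins_after <- if (profile$insertion > 0) runif(n) < profile$insertion
               else FALSE
  backbone <- !is.na(rp)

  ## fast exit: nothing but (possibly substituted) backbone matches
  if (!any(ins_after) && all(kept) && all(backbone)) {
    return(list(seq = paste(bvec, collapse = ""),
                cigar = paste0(n, "M"), ref_start = rp[1]))
  }

  main_op <- character(n)
  main_op[kept & backbone] <- "M"
  main_op[kept & !backbone] <- "I"
  main_op[!kept & backbone] <- "D"
  main_seq <- bvec
  main_seq[!kept] <- ""
  if (length(ins_after) == 1L) ins_after <- rep(ins_after, n)
  ins_op <- character(n)
  ins_op[ins_after] <- "I"
  ins_seq <- character(n)
  if (any(ins_after)) ins_seq[ins_after] <- random_bases(sum(ins_after))

  ops <- as.vector(rbind(main_op, ins_op))
  seqs <- as.vector(rbind(main_seq, ins_seq))
  rps <- as.vector(rbind(rp, rep(NA_integer_, n)))
  keep <- ops != ""
  ops <- ops[keep]; seqs <- seqs[keep]; rps <- rps[keep]

  m_idx <- which(ops == "M")
  if (!length(m_idx)) return(NULL)
  i0 <- m_idx[1]; iN <- m_idx[length(m_idx)]
  ## outside the aligned core: drop D, soft-clip I
  if (i0 > 1L) {
    lead <- seq_len(i0 - 1L)
    drop <- lead[ops[lead] == "D"]
    ops[lead[ops[lead] == "I"]] <- "S"
    if (length(drop)) { ops <- ops[-drop]; seqs <- seqs[-drop]; rps <- rps[-drop] }
  }
  iN <- max(which(ops == "M"))
  if (iN < length(ops)) {
    trail <- seq.int(iN + 1L, length(ops))
    drop <- trail[ops[trail] == "D"]
    ops[trail[ops[trail] == "I"]] <- "S"
    if (length(drop)) { ops <- ops[-drop]; seqs <- seqs[-drop] }
  }
  list(seq = paste(seqs, collapse = ""),
       cigar = cigar_from_ops(ops),
       ref_start = rps[which(ops == "M")[1]])
}

## Shared context for simulating reads off one haplotype.
hap_sim_context <- function(ref, hap) {
  hg <- hap_genome(ref, hap)
  chars <- strsplit(hg$seq, "", fixed = TRUE)[[1]]
  mask <- homopolymer_mask(ref)
  hp_hap <- !is.na(hg$map) & mask[ifelse(is.na(hg$map), 1L, hg$map + 1L)]
  ## amplicon intervals in haplotype coordinates
  amp <- ref$amplicons
  hstart <- hg$ref2hap[amp$start + 1L]
  hend <- hg$ref2hap[amp$end - 1L + 1L] + 1L
  list(chars = chars, map = hg$map, hp = hp_hap,
       amp = data.frame(name = amp$name, hstart = hstart, hend = hend,
                        ref_len = amp$end - amp$start,
                        stringsAsFactors = FALSE))
}

#' Simulate paired short reads from one haplotype
#'
#' Fragments are drawn uniformly within each amplicon (never spanning an
#' amplicon end); each yields a forward first mate and a reverse-strand
#' second mate of `read_len` bases. Errors are injected per base following
#' `profile`. SAM-convention sequences are stored in reference orientation.
#'
#' @param hap a `mito_haplotype`.
#' @param ref the reference genome.
#' @param depth target mean fold-coverage over amplicon interiors.
#' @param read_len read length in bp.
#' @param frag_mean,frag_sd fragment length distribution (normal, clamped to
#'   `[read_len, amplicon length]`).
#' @param profile an [error_profile()].
#' @param seed integer seed.
#' @return Read data frame (one row per mate).
#' @export
simulate_short_reads <- function(hap, ref, depth = 1000, read_len = 250L,
                                 frag_mean = 450, frag_sd = 50,
                                 profile = short_error_profile(),
                                 seed = DEFAULT_SEED) {
  if (frag_mean < read_len)
    stop_config("frag_mean must be >= read_len")
  if (depth <= 0) return(empty_reads())
  ctx <- hap_sim_context(ref, hap)
  qc <- rawToChar(as.raw(33L + QUAL_SHORT))

  withr::with_seed(seed, {
    out <- list()
    for (ai in seq_len(nrow(ctx$amp))) {
      a <- ctx$amp[ai, ]
      amp_len <- a$hend - a$hstart
      npairs <- as.integer(round(depth * a$ref_len / (2 * read_len)))
      if (npairs == 0) next
      flen <- pmin(pmax(as.integer(round(rnorm(npairs, frag_mean, frag_sd))),
                        read_len), amp_len)
      s <- a$hstart + as.integer(floor(runif(npairs) * (amp_len - flen + 1)))
      ids <- sprintf("%s_%s_p%05d", hap$contributor_id, a$name,
                     seq_len(npairs))
      for (i in seq_len(npairs)) {
        w1 <- seq.int(s[i] + 1L, s[i] + read_len)
        w2 <- seq.int(s[i] + flen[i] - read_len + 1L, s[i] + flen[i])
        r1 <- assemble_read(ctx$chars[w1], ctx$map[w1], ctx$hp[w1], profile)
        r2 <- assemble_read(ctx$chars[w2], ctx$map[w2], ctx$hp[w2], profile)
        if (is.null(r1) || is.null(r2)) next
        out[[length(out) + 1L]] <- list(
          read_id = paste0(ids[i], c("/1", "/2")),
          ref_start = c(r1$ref_start, r2$ref_start),
          cigar = c(r1$cigar, r2$cigar),
          seq = c(r1$seq, r2$seq),
          strand = c("+", "-"),
          pair_id = c(ids[i], ids[i]),
          mate = c(1L, 2L))
      }
    }
    if (!length(out)) return(empty_reads())
    df <- data.frame(
      read_id = unlist(lapply(out, `[[`, "read_id")),
      contributor = hap$contributor_id,
      platform = "SHORT",
      ref_start = unlist(lapply(out, `[[`, "ref_start")),
      cigar = unlist(lapply(out, `[[`, "cigar")),
      seq = unlist(lapply(out, `[[`, "seq")),
      qual = NA_character_,
      strand = unlist(lapply(out, `[[`, "strand")),
      pair_id = unlist(lapply(out, `[[`, "pair_id")),
      mate = unlist(lapply(out, `[[`, "mate")),
      secondary = FALSE, mapped = TRUE,
      stringsAsFactors = FALSE)
    df$qual <- strrep(qc, nchar(df$seq))
    df
  })
}

#' Simulate single-molecule long reads from one haplotype
#'
#' A fraction `1 - truncated_fraction` of molecules span a full amplicon;
#' the rest are forward-strand partial products starting at the amplicon's
#' forward primer with lengths uniform in 500--4000 bp (failed extensions /
#' early terminations). The profile's `homopolymer_extra_deletion` rate
#' applies inside annotated runs.
#'
#' @inheritParams simulate_short_reads
#' @param truncated_fraction proportion of truncated molecules in `[0, 1]`.
#' @return Read data frame (unpaired).
#' @export
simulate_long_reads <- function(hap, ref, depth = 300,
                                profile = long_error_profile(),
                                truncated_fraction = 0.3,
                                seed = DEFAULT_SEED) {
  if (truncated_fraction < 0 || truncated_fraction > 1)
    stop_config("truncated_fraction must lie in [0, 1]")
  if (depth <= 0) return(empty_reads())
  ctx <- hap_sim_context(ref, hap)
  qc <- rawToChar(as.raw(33L + QUAL_LONG))

  withr::with_seed(seed, {
    out <- list()
    for (ai in seq_len(nrow(ctx$amp))) {
      a <- ctx$amp[ai, ]
      amp_len <- a$hend - a$hstart
      mean_len <- (1 - truncated_fraction) * amp_len +
        truncated_fraction * mean(c(500, 4000))
      n_mol <- as.integer(round(depth * a$ref_len / mean_len))
      if (n_mol == 0) next
      trunc <- runif(n_mol) < truncated_fraction
      lens <- ifelse(trunc,
                     pmin(as.integer(round(runif(n_mol, 500, 4000))), amp_len),
                     amp_len)
      strands <- ifelse(trunc, "+", sample(c("+", "-"), n_mol, replace = TRUE))
      for (i in seq_len(n_mol)) {
        w <- seq.int(a$hstart + 1L, a$hstart + lens[i])
        r <- assemble_read(ctx$chars[w], ctx$map[w], ctx$hp[w], profile)
        if (is.null(r)) next
        out[[length(out) + 1L]] <- list(
          read_id = sprintf("%s_%s_L%05d", hap$contributor_id, a$name, i),
          ref_start = r$ref_start, cigar = r$cigar, seq = r$seq,
          strand = strands[i])
      }
    }
    if (!length(out)) return(empty_reads())
    df <- data.frame(
      read_id = vapply(out, `[[`, character(1), "read_id"),
      contributor = hap$contributor_id,
      platform = "LONG",
      ref_start = vapply(out, `[[`, integer(1), "ref_start"),
      cigar = vapply(out, `[[`, character(1), "cigar"),
      seq = vapply(out, `[[`, character(1), "seq"),
      qual = NA_character_,
      strand = vapply(out, `[[`, character(1), "strand"),
      pair_id = NA_character_, mate = NA_integer_,
      secondary = FALSE, mapped = TRUE,
      stringsAsFactors = FALSE)
    df$qual <- strrep(qc, nchar(df$seq))
    df
  })
}

#' Simulate a two-contributor mixture on both platforms
#'
#' Molecules are drawn from each contributor in the stated ratio; per-read
#' truth labels are retained. Depths are the totals across contributors.
#'
#' @param hapA,hapB the two `mito_haplotype`s.
#' @param ref the reference genome.
#' @param ratio length-2 molecule proportions summing to 1.
#' @param short_depth,long_depth total fold-coverages per platform.
#' @param short_profile,long_profile platform [error_profile()]s.
#' @param truncated_fraction long-read truncation proportion.
#' @param read_len,frag_mean,frag_sd short-read library settings.
#' @param seed integer seed (contributor streams are derived from it).
#' @return List with elements `short` and `long`, each a read data frame.
#' @export
simulate_mixture <- function(hapA, hapB, ref, ratio = c(0.5, 0.5),
                             short_depth = 1000, long_depth = 300,
                             short_profile = short_error_profile(),
                             long_profile = long_error_profile(),
                             truncated_fraction = 0.3,
                             read_len = 250L, frag_mean = 450, frag_sd = 50,
                             seed = DEFAULT_SEED) {
  if (abs(sum(ratio) - 1) > 1e-8 || any(ratio < 0))
    stop_config("mixture ratio must be non-negative and sum to 1")
  haps <- list(hapA, hapB)
  short <- list(); long <- list()
  for (i in 1:2) {
    if (ratio[i] == 0) next
    short[[length(short) + 1L]] <- simulate_short_reads(
      haps[[i]], ref, depth = short_depth * ratio[i], read_len = read_len,
      frag_mean = frag_mean, frag_sd = frag_sd, profile = short_profile,
      seed = derive_seed(seed, 10L + i))
    long[[length(long) + 1L]] <- simulate_long_reads(
      haps[[i]], ref, depth = long_depth * ratio[i], profile = long_profile,
      truncated_fraction = truncated_fraction,
      seed = derive_seed(seed, 20L + i))
  }
  list(short = do.call(rbind, c(list(empty_reads()), short)),
       long = do.call(rbind, c(list(empty_reads()), long)))
}
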