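## Contributor haplotypes: a shared backbone of SNPs carried by both
## contributors (same haplogroup) plus private SNPs and private insertions
## that distinguish them. These variant lists are the simulation ground
## truth; truth tables are written in a minimal VCF-like tab format.

MIN_VARIANT_SPACING <- 15L

#' Generate two same-backbone contributor haplotypes
#'
#' Both haplotypes carry an identical set of `n_shared` backbone SNPs; each
#' additionally carries its own private SNPs and private insertions. With the
#' defaults (31 shared, 6 private SNPs and 1 private insertion per
#' contributor) the union of the two call sets holds 31 shared SNPs, 12
#' private SNPs and 2 private insertions. At least one private SNP of the
#' first contributor is planted inside an annotated homopolymer run so the
#' long-read error mode is exercised at a truth site.
#'
#' Placement avoids primer intervals, a 300 bp margin at the two linear
#' genome ends, and enforces a minimum spacing between variants. Insertions
#' are generated already left-aligned (the inserted sequence never ends in
#' the anchor base).
#'
#' @param ref a [generate_reference()] genome.
#' @param n_shared shared backbone SNP count.
#' @param n_private_snps_each private SNPs per contributor.
#' @param n_private_ins_each private insertions per contributor.
#' @param seed integer seed.
#' @param ids length-2 character vector of contributor labels.
#' @return List of two `mito_haplotype` objects (`contributor_id`, `shared`
#'   and `private` variant data frames with 0-based `pos`, `ref`, `alt`,
#'   `vclass`).
#' @export
generate_haplotypes <- function(ref, n_shared = 31L, n_private_snps_each = 6L,
                                n_private_ins_each = 1L, seed = DEFAULT_SEED,
                                ids = c("A", "B")) {
  stopifnot(length(ids) == 2, ids[1] != ids[2])
  n_total <- n_shared + 2L * (n_private_snps_each + n_private_ins_each)
  chars <- ref_chars(ref)
  hp_mask <- homopolymer_mask(ref)

  forbidden <- logical(ref$length)
  forbidden[primer_positions(ref) + 1L] <- TRUE
  forbidden[seq_len(min(EDGE_MARGIN, ref$length))] <- TRUE
  forbidden[seq.int(max(1L, ref$length - EDGE_MARGIN + 1L), ref$length)] <- TRUE

  if (sum(!forbidden) < n_total * MIN_VARIANT_SPACING)
    stop_config("genome too small for ", n_total, " variants")

  withr::with_seed(seed, {
    taken <- integer(0)
    draw_pos <- function(candidates) {
      for (try in 1:500) {
        p <- candidates[sample.int(length(candidates), 1L)]
        if (!forbidden[p + 1L] && !any(abs(p - taken) < MIN_VARIANT_SPACING)) {
          taken <<- c(taken, p)
          return(p)
        }
      }
      stop_config("variant placement failed after bounded retries")
    }
    all_pos <- seq.int(0L, ref$length - 1L)

    snp_at <- function(pos) {
      rb <- chars[pos + 1L]
      data.frame(pos = pos, ref = rb,
                 alt = sample(setdiff(DNA_BASES, rb), 1L),
                 vclass = "SNP", stringsAsFactors = FALSE)
    }
    ins_at <- function(pos) {
      rb <- chars[pos + 1L]
      repeat {
        s <- paste(random_bases(2L), collapse = "")
        ## keep the record left-aligned: inserted seq must not end in anchor
        if (substr(s, 2L, 2L) != rb) break
      }
      data.frame(pos = pos, ref = rb, alt = paste0(rb, s),
                 vclass = "INS", stringsAsFactors = FALSE)
    }

    shared <- do.call(rbind, c(list(snp_at(draw_pos(all_pos))[0, ]),
                               lapply(seq_len(n_shared),
                                      function(i) snp_at(draw_pos(all_pos)))))

    make_private <- function(force_homopolymer) {
      rows <- list()
      n_snp <- n_private_snps_each
      if (force_homopolymer && n_snp > 0 && any(hp_mask & !forbidden)) {
        pos <- draw_pos(which(hp_mask & !forbidden) - 1L)
        rows <- c(rows, list(snp_at(pos)))
        n_snp <- n_snp - 1L
      }
      rows <- c(rows, lapply(seq_len(n_snp), function(i) snp_at(draw_pos(all_pos))))
      rows <- c(rows, lapply(seq_len(n_private_ins_each),
                             function(i) ins_at(draw_pos(all_pos))))
      out <- do.call(rbind, c(list(shared[0, ]), rows))
      out[order(out$pos), , drop = FALSE]
    }

    privA <- make_private(force_homopolymer = TRUE)
    privB <- make_private(force_homopolymer = FALSE)
    shared <- shared[order(shared$pos), , drop = FALSE]
    rownames(shared) <- rownames(privA) <- rownames(privB) <- NULL

    list(
      structure(list(contributor_id = ids[1], shared = shared, private = privA),
                class = "mito_haplotype"),
      structure(list(contributor_id = ids[2], shared = shared, private = privB),
                class = "mito_haplotype")
    )
  })
}

#' @export
print.mito_haplotype <- function(x, ...) {
  cat("mito_haplotype '", x$contributor_id, "': ", nrow(x$shared),
      " shared + ", nrow(x$private), " private variant(s)\n", sep = "")
  invisible(x)
}

#' All variants carried by a haplotype
#' @param hap a `mito_haplotype`.
#' @return Variant data frame sorted by position.
#' @export
hap_variants <- function(hap) {
  v <- rbind(hap$shared, hap$private)
  v <- v[order(v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Materialise a haplotype sequence and its reference alignment
#'
#' Applies the haplotype's SNPs and insertions to the reference and returns
#' the haplotype sequence together with the base-level alignment used by the
#' simulator: `map[i]` is the 0-based reference position aligned to haplotype
#' base `i` (NA for inserted bases), and `ref2hap[r + 1]` is the haplotype
#' coordinate of reference position `r`.
#'
#' @param ref a `mito_reference`.
#' @param hap a `mito_haplotype`.
#' @return List with `seq` (character), `map` (integer vector), `ref2hap`.
#' @export
hap_genome <- function(ref, hap) {
  v <- hap_variants(hap)
  chars <- ref_chars(ref)
  snps <- v[v$vclass == "SNP", , drop = FALSE]
  if (nrow(snps)) {
    stopifnot(all(chars[snps$pos + 1L] == snps$ref))
    chars[snps$pos + 1L] <- snps$alt
  }
  ins <- v[v$vclass == "INS", , drop = FALSE]
  map <- seq.int(0L, ref$length - 1L)
  if (nrow(ins)) {
    ins <- ins[order(ins$pos), , drop = FALSE]
    pieces_seq <- list()
    pieces_map <- list()
    prev <- 0L
    for (i in seq_len(nrow(ins))) {
      a <- ins$pos[i]
      inserted <- substr(ins$alt[i], 2L, nchar(ins$alt[i]))
      pieces_seq <- c(pieces_seq, list(chars[(prev + 1L):(a + 1L)]),
                      list(strsplit(inserted, "")[[1]]))
      pieces_map <- c(pieces_map, list(prev:a),
                      list(rep(NA_integer_, nchar(inserted))))
      prev <- a + 1L
    }
    if (prev <= ref$length - 1L) {
      pieces_seq <- c(pieces_seq, list(chars[(prev + 1L):ref$length]))
      pieces_map <- c(pieces_map, list(prev:(ref$length - 1L)))
    }
    chars <- unlist(pieces_seq)
    map <- unlist(pieces_map)
  }
  ref2hap <- which(!is.na(map))[order(map[!is.na(map)])] - 1L
  list(seq = paste(chars, collapse = ""), map = map, ref2hap = ref2hap)
}

#' Write a truth variant table
#'
#' Tab-separated VCF-like format: CHROM, POS (1-based), REF, ALT, CLASS,
#' SHARING (`shared` or `private:<contributor>`).
#'
#' @param haps list of two `mito_haplotype`s.
#' @param ref the reference genome.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_truth_table <- function(haps, ref, path) {
  rows <- lapply(haps, function(h) {
    rbind(
      if (nrow(h$shared)) cbind(h$shared, SHARING = "shared"),
      if (nrow(h$private)) cbind(h$private,
                                 SHARING = paste0("private:", h$contributor_id))
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(paste(tab$pos, tab$alt, tab$SHARING)), , drop = FALSE]
  tab <- tab[order(tab$pos), , drop = FALSE]
  out <- data.frame(CHROM = ref$name, POS = tab$pos + 1L, REF = tab$ref,
                    ALT = tab$alt, CLASS = tab$vclass, SHARING = tab$SHARING,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth variant table
#' @param path file written by [write_truth_table()].
#' @return Data frame with 0-based `pos`, `ref`, `alt`, `vclass`, `sharing`.
#' @export
read_truth_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "character",
                                 "character", "character", "character"))
  data.frame(pos = x$POS - 1L, ref = x$REF, alt = x$ALT, vclass = x$CLASS,
             sharing = x$SHARING, stringsAsFactors = FALSE)
}
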