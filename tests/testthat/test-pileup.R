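test_that("CIGAR ops route bases, deletions and insertions correctly", {
  ref <- tiny_ref()
  # one read, 10M at 5 -> depth 1 over [5, 15), 0 elsewhere
  r <- mk_reads(5, "10M", substr(ref$sequence, 6, 15))
  p <- build_pileup(r, ref)
  expect_equal(which(p$depth == 1) - 1, 5:14)
  expect_equal(sum(p$depth), 10)

  # 5M2D5M at 0 -> deletion_count 1 at 5 and 6, bases at 0-4 and 7-11
  seq10 <- paste0(substr(ref$sequence, 1, 5), substr(ref$sequence, 8, 12))
  p2 <- build_pileup(mk_reads(0, "5M2D5M", seq10), ref)
  expect_equal(p2$del[5:6 + 1], c(1, 1))
  expect_equal(which(colSums(p2$counts) == 1) - 1, c(0:4, 7:11))
  expect_equal(p2$depth[0:11 + 1], rep(1, 12))

  # insertion anchored at the preceding reference base: 3M2I3M at 10
  ins_seq <- paste0(substr(ref$sequence, 11, 13), "AC", substr(ref$sequence, 14, 16))
  p3 <- build_pileup(mk_reads(10, "3M2I3M", ins_seq), ref)
  expect_equal(p3$ins$pos, 12)
  expect_equal(p3$ins$seq, "AC")

  # soft clips contribute nothing
  p4 <- build_pileup(mk_reads(20, "5S5M", strrep("A", 10)), ref)
  expect_equal(sum(p4$depth), 5)

  # read past the reference end is rejected
  expect_error(build_pileup(mk_reads(ref$length - 3, "10M", strrep("A", 10)),
                            ref), "past reference end")

  # secondary/unmapped reads are excluded
  r5 <- mk_reads(c(5, 5, 5), rep("10M", 3), rep(substr(ref$sequence, 6, 15), 3),
                 secondary = c(FALSE, TRUE, FALSE),
                 mapped = c(TRUE, TRUE, FALSE))
  expect_equal(max(build_pileup(r5, ref)$depth), 1)
})

test_that("column depth equals covering reads (brute-force oracle)", {
  ref <- tiny_ref()
  hap <- tiny_haps()[[1]]
  reads <- simulate_long_reads(hap, ref, 2,
                               error_profile(substitution = 0.05,
                                             insertion = 0.05,
                                             deletion = 0.05),
                               truncated_fraction = 0.8, seed = 77)
  reads <- reads[seq_len(min(15, nrow(reads))), ]
  p <- build_pileup(reads, ref)
  parsed <- parse_cigar(reads$cigar)
  for (pos in seq(0, ref$length - 1, by = 97)) {
    covering <- 0L
    for (i in seq_len(nrow(reads))) {
      hit <- mitomix:::read_base_at(reads$ref_start[i], parsed[[i]],
                                    reads$seq[i], pos)
      if (!is.na(hit$op)) covering <- covering + 1L
    }
    expect_equal(p$depth[pos + 1], covering)
  }
  # conservation: depth = base counts + deletions everywhere
  expect_equal(p$depth, as.integer(colSums(p$counts)) + p$del)
})

test_that("VAF uses all covering reads in the denominator", {
  # mixture locus: A 146, G 180, other 14 (8 T + 6 deleted) -> depth 340
  col <- list(pos = 3848, counts = c(A = 146, C = 0, G = 180, T = 8),
              depth = 340)
  expect_equal(round(vaf(col, "A"), 4), 0.4294)
  expect_equal(mitomix:::as_percent(vaf(col, "A")), 43)
  expect_equal(mitomix:::as_percent(vaf(col, "G")), 53)

  # private alternate at low fraction: T 951, C 178, other 6 -> 0.16
  col2 <- list(pos = 4735, counts = c(A = 2, C = 178, G = 4, T = 951),
               depth = 1135)
  expect_equal(round(vaf(col2, "C"), 2), 0.16)

  expect_equal(vaf(list(pos = 1, counts = c(A = 0, C = 0, G = 50, T = 0),
                        depth = 50), "A"), 0)
  expect_error(vaf(list(pos = 9, counts = c(A = 0, C = 0, G = 0, T = 0),
                        depth = 0), "A"), "depth 0")
})

test_that("SNP calling respects threshold, depth floor, SNP-only rule and ploidy", {
  ref <- tiny_ref()
  chars <- strsplit(ref$sequence, "")[[1]]
  pos <- 1000L
  alt <- setdiff(c("A", "C", "G", "T"), chars[pos + 1])[1]
  # 43 alt reads of 100 covering pos
  base_reads <- mk_reads(rep(990, 100), rep("20M", 100),
                         rep(substr(ref$sequence, 991, 1010), 100))
  alt_seq <- base_reads$seq[1]
  substr(alt_seq, 11, 11) <- alt
  base_reads$seq[1:43] <- alt_seq
  p <- build_pileup(base_reads, ref)
  expect_equal(nrow(call_snps(p, ref, 0.45, 20)), 0)
  c40 <- call_snps(p, ref, 0.40, 20)
  expect_equal(c40$pos, pos)
  expect_equal(c40$alt, alt)

  # depth floor: same column fails a min_depth above its coverage
  expect_equal(nrow(call_snps(p, ref, 0.40, 200)), 0)

  # a pure deletion signal at 90% is never emitted as a SNP
  del_reads <- mk_reads(rep(500, 20), c(rep("10M5D10M", 18), rep("25M", 2)),
                        c(rep(paste0(substr(ref$sequence, 501, 510),
                                     substr(ref$sequence, 516, 525)), 18),
                          rep(substr(ref$sequence, 501, 525), 2)))
  pd <- build_pileup(del_reads, ref)
  expect_gt(pd$del[511] / pd$depth[511], 0.85)
  expect_equal(nrow(call_snps(pd, ref, 0.5, 10)), 0)

  # ploidy: single_source keeps the top alternate, mixture keeps two
  two_alt <- base_reads
  alt2 <- setdiff(c("A", "C", "G", "T"), c(chars[pos + 1], alt))[1]
  alt2_seq <- base_reads$seq[100]
  substr(alt2_seq, 11, 11) <- alt2
  two_alt$seq[44:83] <- alt2_seq
  p2 <- build_pileup(two_alt, ref)
  expect_equal(nrow(call_snps(p2, ref, 0.3, 20, "single_source")), 1)
  expect_equal(nrow(call_snps(p2, ref, 0.3, 20, "mixture")), 2)
})

test_that("call sets nest across thresholds and recover a clean single source", {
  ref <- tiny_ref()
  hap <- tiny_haps()[[1]]
  # noisy pileup: nesting must hold on every adjacent threshold pair
  noisy <- simulate_short_reads(hap, ref, 80, 100L, 200, 20,
                                error_profile(substitution = 0.1), seed = 55)
  p <- build_pileup(noisy, ref)
  thr <- vaf_thresholds(0.05, 0.95, 0.05)
  calls <- lapply(thr, function(t) {
    cs <- call_snps(p, ref, t, 20)
    paste(cs$pos, cs$alt)
  })
  for (i in seq_len(length(thr) - 1)) {
    expect_true(all(calls[[i + 1]] %in% calls[[i]]))
  }
  # every call's VAF is at or above its threshold
  c50 <- call_snps(p, ref, 0.5, 20)
  expect_true(all(c50$vaf >= 0.5))

  # zero-error single source at >= 50x, called at 0.9, equals the truth SNPs
  clean <- simulate_short_reads(hap, ref, 60, 100L, 200, 20,
                                zero_error_profile(), seed = 56)
  cs <- call_snps(build_pileup(clean, ref), ref, 0.9, 20)
  tv <- truth_snps(hap)
  expect_setequal(paste(cs$pos, cs$alt), paste(tv$pos, tv$alt))
})

test_that("left-alignment decomposes blocks and shifts indels to run starts", {
  ref <- tiny_ref()
  chars <- strsplit(ref$sequence, "")[[1]]

  # block substitution -> per-position SNPs
  p <- 1200L
  refblock <- substr(ref$sequence, p + 1, p + 2)
  altblock <- chartr("ACGT", "GTAC", refblock)
  out <- left_align_and_decompose(
    data.frame(pos = p, ref = refblock, alt = altblock), ref)
  expect_equal(out$pos, c(p, p + 1))
  expect_equal(out$vclass, c("SNP", "SNP"))
  expect_equal(out$alt, strsplit(altblock, "")[[1]])

  # insertion of the run base inside a homopolymer run shifts to the run's
  # leftmost anchor; expected anchor computed by an independent scan for the
  # start of the maximal run ending at the insertion point
  hp <- ref$homopolymers[1, ]
  p_ins <- hp$start + hp$length - 1L      # last base of the run
  t <- hp$start
  while (t > 0 && chars[t] == hp$base) t <- t - 1L
  expected_anchor <- t - 1L
  v <- data.frame(pos = p_ins, ref = chars[p_ins + 1],
                  alt = paste0(chars[p_ins + 1], hp$base))
  out2 <- left_align_and_decompose(v, ref)
  expect_equal(out2$pos, expected_anchor)
  expect_equal(out2$vclass, "INS")
  expect_equal(out2$alt, paste0(chars[expected_anchor + 1], hp$base))

  # deletion inside the run shifts the same way
  vd <- data.frame(pos = p_ins - 1L,
                   ref = substr(ref$sequence, p_ins, p_ins + 1),
                   alt = chars[p_ins])
  out3 <- left_align_and_decompose(vd, ref)
  expect_equal(out3$pos, expected_anchor)
  expect_equal(out3$vclass, "DEL")

  # multi-allelic records split into biallelic records
  out4 <- left_align_and_decompose(
    data.frame(pos = p, ref = chars[p + 1],
               alt = paste(setdiff(c("A", "C", "G", "T"), chars[p + 1])[1:2],
                           collapse = ",")), ref)
  expect_equal(nrow(out4), 2)

  # idempotence
  again <- left_align_and_decompose(out2[, c("pos", "ref", "alt")], ref)
  expect_equal(again$pos, out2$pos)
  expect_equal(again$alt, out2$alt)

  # reference mismatch is a consistency error
  wrong <- setdiff(c("A", "C", "G", "T"), chars[p + 1])[1]
  expect_error(left_align_and_decompose(
    data.frame(pos = p, ref = wrong, alt = chars[p + 1]), ref), "mismatch")
})
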