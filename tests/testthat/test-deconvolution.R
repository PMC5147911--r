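test_that("SNP verdicts require an M op and a matching contributor allele", {
  ref <- tiny_ref()
  pos <- 1500L
  chars <- strsplit(ref$sequence, "")[[1]]
  aA <- setdiff(c("A", "C", "G", "T"), chars[pos + 1])[1]
  aB <- chars[pos + 1]
  third <- setdiff(c("A", "C", "G", "T"), c(aA, aB))[1]
  site <- list(pos = pos, allele_A = aA, allele_B = aB)

  read_with <- function(base) {
    s <- substr(ref$sequence, pos - 20 + 1, pos + 20)
    substr(s, 21, 21) <- base
    mk_reads(pos - 20, "41M", s, pair_id = "p1", mate = 1L)
  }
  expect_equal(assign_pair_by_snp(read_with(aB), site), "B")
  expect_equal(assign_pair_by_snp(read_with(aA), site), "A")
  expect_equal(assign_pair_by_snp(read_with(third), site), "no_evidence")

  # site under a D op gives no evidence
  del_read <- mk_reads(pos - 20, "18M5D18M",
                       paste0(substr(ref$sequence, pos - 19, pos - 2),
                              substr(ref$sequence, pos + 4, pos + 21)),
                       pair_id = "p1", mate = 1L)
  expect_equal(assign_pair_by_snp(del_read, site), "no_evidence")

  # neither mate covering is a caller error
  expect_error(assign_pair_by_snp(mk_reads(0, "10M", strrep("A", 10),
                                           pair_id = "p1", mate = 1L), site),
               "covers")
})

test_that("insertion verdicts use the 10 bp window and the I op at the anchor", {
  pos <- 50L
  ins <- list(pos = pos, seq = "TT", carrier = "A")
  # covers [30, 80): window satisfied, I anchored at 50 -> carrier
  with_ins <- mk_reads(30, "21M2I29M", strrep("A", 52), pair_id = "p", mate = 1L)
  expect_equal(assign_pair_by_insertion(with_ins, ins, other = "B"), "A")
  # window satisfied, pure M -> the other contributor
  no_ins <- mk_reads(30, "50M", strrep("A", 50), pair_id = "p", mate = 1L)
  expect_equal(assign_pair_by_insertion(no_ins, ins, other = "B"), "B")
  # covers only pos-3 .. pos+4: window not satisfied
  narrow <- mk_reads(pos - 3, "8M", strrep("A", 8), pair_id = "p", mate = 1L)
  expect_equal(assign_pair_by_insertion(narrow, ins, other = "B"),
               "no_evidence")
  # I at the wrong anchor does not attribute to the carrier
  wrong_anchor <- mk_reads(30, "10M2I40M", strrep("A", 52),
                           pair_id = "p", mate = 1L)
  expect_equal(assign_pair_by_insertion(wrong_anchor, ins, other = "B"), "B")
})

test_that("pairs are routed by majority vote with ties going to shared", {
  ref <- tiny_ref()
  h <- tiny_haps()
  panel <- tiny_panel()
  expect_gt(nrow(panel$snps), 0)

  s1 <- panel$snps[1, ]; s2 <- panel$snps[2, ]
  span_read <- function(pos, base, pair_id, mate = 1L) {
    s <- substr(ref$sequence, pos - 20 + 1, pos + 20)
    substr(s, 21, 21) <- base
    mk_reads(pos - 20, "41M", s, pair_id = pair_id, mate = mate,
             read_id = paste0(pair_id, "/", mate))
  }
  pairs <- rbind(
    span_read(s1$pos, s1$allele_A, "pa", 1L),  # two A verdicts -> pool A
    span_read(s2$pos, s2$allele_A, "pa", 2L),
    span_read(s1$pos, s1$allele_A, "pt", 1L),  # A + B verdicts -> shared
    span_read(s2$pos, s2$allele_B, "pt", 2L),
    span_read(s1$pos, s1$allele_B, "pb", 1L),  # lone B verdict -> pool B
    mk_reads(0, "10M", substr(ref$sequence, 1, 10), pair_id = "pb",
             mate = 2L, read_id = "pb/2"))
  asg <- deconvolve(pairs, panel)
  expect_setequal(unique(asg$pool_A$pair_id), "pa")
  expect_setequal(unique(asg$pool_B$pair_id), "pb")
  expect_setequal(unique(asg$shared$pair_id), "pt")
  expect_equal(nrow(asg$pool_A) + nrow(asg$pool_B) + nrow(asg$shared),
               nrow(pairs))
  expect_true(all(c("pa", "pt", "pb") %in% asg$evidence$pair_id))

  # empty panel: everything shared, with a warning
  empty_panel <- structure(list(snps = panel$snps[0, ],
                                insertions = panel$insertions[0, ],
                                labels = c("A", "B")), class = "mito_panel")
  expect_warning(asg0 <- deconvolve(pairs, empty_panel), "empty panel")
  expect_equal(nrow(asg0$shared), nrow(pairs))
})

test_that("a clean 1:1 mixture deconvolves with perfect pool purity", {
  mix <- tiny_mixture_clean()
  panel <- tiny_panel()
  asg <- deconvolve(mix$short, panel)
  expect_gt(nrow(asg$pool_A), 100)
  expect_gt(nrow(asg$pool_B), 100)
  expect_true(all(asg$pool_A$contributor == "A"))
  expect_true(all(asg$pool_B$contributor == "B"))
  # three-pool partition: no pair lost or duplicated
  expect_setequal(c(asg$pool_A$read_id, asg$pool_B$read_id, asg$shared$read_id),
                  mix$short$read_id)

  # panel label swap swaps the private pools exactly
  sw <- structure(list(
    snps = data.frame(pos = panel$snps$pos, allele_A = panel$snps$allele_B,
                      allele_B = panel$snps$allele_A),
    insertions = data.frame(pos = panel$insertions$pos,
                            seq = panel$insertions$seq,
                            carrier = ifelse(panel$insertions$carrier == "A",
                                             "B", "A")),
    labels = c("A", "B")), class = "mito_panel")
  asg_sw <- deconvolve(mix$short, sw)
  expect_setequal(asg_sw$pool_A$read_id, asg$pool_B$read_id)
  expect_setequal(asg_sw$pool_B$read_id, asg$pool_A$read_id)
})

test_that("deconvolved sets concentrate private alleles towards VAF 1", {
  ref <- tiny_ref()
  h <- tiny_haps()
  mix <- tiny_mixture_clean()
  panel <- tiny_panel()
  asg <- deconvolve(mix$short, panel)
  sets <- build_deconvolved_sets(asg)
  expect_equal(nrow(sets$A),
               nrow(asg$pool_A) + nrow(asg$shared))
  expect_equal(nrow(sets$B),
               nrow(asg$pool_B) + nrow(asg$shared))

  p_mix <- build_pileup(mix$short, ref)
  p_A <- build_pileup(sets$A, ref)
  privA <- h[[1]]$private[h[[1]]$private$vclass == "SNP", ]
  for (i in seq_len(nrow(privA))) {
    v_mix <- vaf(pileup_column(p_mix, privA$pos[i]), privA$alt[i])
    v_dec <- vaf(pileup_column(p_A, privA$pos[i]), privA$alt[i])
    expect_lt(abs(v_mix - 0.5), 0.1)
    expect_gt(v_dec, 0.95)
  }

  # empty private pools: both sets equal the shared pool
  empty <- structure(list(pool_A = mix$short[0, ], pool_B = mix$short[0, ],
                          shared = mix$short, evidence = NULL),
                     class = "mito_assignment")
  sets0 <- build_deconvolved_sets(empty)
  expect_equal(nrow(sets0$A), nrow(mix$short))
  expect_identical(sets0$A$read_id, sets0$B$read_id)
})

test_that("FASTQ export keeps whole proper pairs in sequencing orientation", {
  ref <- tiny_ref()
  reads <- simulate_short_reads(tiny_haps()[[1]], ref, 8, 100L, 200, 20,
                                zero_error_profile(), seed = 91)
  pairs <- unique(reads$pair_id)[1:11]
  sub <- reads[reads$pair_id %in% pairs, ]
  sub <- sub[!(sub$pair_id == pairs[11] & sub$mate == 2L), ]  # orphan mate
  sub$secondary[sub$pair_id == pairs[10]] <- TRUE             # secondary pair
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  res <- export_fastq(sub, r1, r2)
  expect_equal(res$n_pairs, 9)
  expect_true(pairs[11] %in% res$orphans)
  fq1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  fq2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  expect_length(fq1, 9)
  expect_length(fq2, 9)

  # round trip: R1 equals SAM seq (forward mate), R2 is the reverse
  # complement of the SAM-stored reverse-strand mate
  for (pid in pairs[1:3]) {
    m1 <- sub[sub$pair_id == pid & sub$mate == 1L, ]
    m2 <- sub[sub$pair_id == pid & sub$mate == 2L, ]
    expect_equal(as.character(fq1[[paste0(pid, "/1")]]), m1$seq)
    expect_equal(as.character(fq2[[paste0(pid, "/2")]]),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(m2$seq))))
  }
})
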