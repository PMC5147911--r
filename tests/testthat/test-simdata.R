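test_that("reference generation is deterministic and annotations match the sequence", {
  r1 <- generate_reference(16569, 3, 6, seed = 7)
  r2 <- generate_reference(16569, 3, 6, seed = 7)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$homopolymers, r2$homopolymers)

  expect_equal(r1$length, 16569)
  expect_equal(nrow(r1$homopolymers), 3)
  expect_true(all(r1$homopolymers$length >= 6))
  chars <- strsplit(r1$sequence, "")[[1]]
  for (i in seq_len(nrow(r1$homopolymers))) {
    run <- chars[(r1$homopolymers$start[i] + 1):(r1$homopolymers$start[i] +
                                                   r1$homopolymers$length[i])]
    expect_true(all(run == r1$homopolymers$base[i]))
  }

  # amplicon geometry: sizes ~8.3/8.6 kb, joint cover, interior overlap
  a <- r1$amplicons
  expect_equal(a$end[a$name == "amp1"] - a$start[a$name == "amp1"], 8300)
  expect_equal(a$end[a$name == "amp2"] - a$start[a$name == "amp2"], 8600)
  expect_equal(min(a$start), 0)
  expect_equal(max(a$end), r1$length)
  expect_lt(a$start[a$name == "amp1"], a$end[a$name == "amp2"])  # overlap

  r0 <- generate_reference(16569, 0, 6, seed = 7)
  expect_equal(nrow(r0$homopolymers), 0)

  expect_error(generate_reference(500), "too small")
  expect_error(generate_reference(16569, min_run = 3), "min_run")
})

test_that("haplotypes carry the configured shared/private variant structure", {
  h <- full_haps()
  expect_equal(nrow(h[[1]]$shared), 31)
  expect_identical(h[[1]]$shared, h[[2]]$shared)

  privA <- h[[1]]$private
  privB <- h[[2]]$private
  expect_equal(sum(privA$vclass == "SNP") + sum(privB$vclass == "SNP"), 12)
  expect_equal(sum(privA$vclass == "INS") + sum(privB$vclass == "INS"), 2)
  expect_length(intersect(privA$pos, privB$pos), 0)
  expect_length(intersect(privA$pos, h[[1]]$shared$pos), 0)
  expect_length(intersect(privB$pos, h[[1]]$shared$pos), 0)

  # at least one private SNP sits inside a planted homopolymer run
  mask <- mitomix:::homopolymer_mask(full_ref())
  expect_true(any(mask[privA$pos[privA$vclass == "SNP"] + 1]))

  # placement avoids primers and the linear-end margins
  allpos <- c(h[[1]]$shared$pos, privA$pos, privB$pos)
  expect_false(any(allpos %in% mitomix:::primer_positions(full_ref())))
  expect_true(all(allpos >= 300 & allpos < full_ref()$length - 300))

  # degenerate: no variants -> haplotypes identical to the reference
  h0 <- generate_haplotypes(full_ref(), 0, 0, 0, seed = 1)
  expect_equal(nrow(hap_variants(h0[[1]])), 0)
  expect_identical(hap_genome(full_ref(), h0[[1]])$seq, full_ref()$sequence)

  # shared sets equal as sets, private sets pairwise disjoint
  h2 <- generate_haplotypes(full_ref(), 5, 2, 0, seed = 1)
  expect_setequal(paste(h2[[1]]$shared$pos, h2[[1]]$shared$alt),
                  paste(h2[[2]]$shared$pos, h2[[2]]$shared$alt))
  expect_length(intersect(h2[[1]]$private$pos, h2[[2]]$private$pos), 0)
})

test_that("short-read simulation honours depth, pairing and the no-noise contract", {
  ref <- tiny_ref()
  hap <- tiny_haps()[[1]]
  reads <- simulate_short_reads(hap, ref, depth = 60, read_len = 100L,
                                frag_mean = 200, frag_sd = 20,
                                profile = zero_error_profile(), seed = 3)
  validate_reads(reads, ref)
  expect_true(all(nchar(reads$seq) == 100))
  expect_true(all(table(reads$pair_id) == 2))
  expect_true(all(reads$contributor == hap$contributor_id))

  # mean coverage over amplicon interiors within 20% of request
  cov <- coverage_track(reads, ref)$depth
  interior <- (ref$amplicons$start[1] + 300):(ref$amplicons$end[1] - 300)
  expect_lt(abs(mean(cov[interior + 1]) - 60) / 60, 0.2)

  # zero-error reads match the haplotype over M segments (pure-M reads
  # equal the haplotype substring at their position)
  hg <- hap_genome(ref, hap)
  pure <- reads[grepl("^[0-9]+M$", reads$cigar), ]
  pick <- pure[seq(1, nrow(pure), length.out = 50), ]
  for (i in seq_len(nrow(pick))) {
    hstart <- hg$ref2hap[pick$ref_start[i] + 1]
    expect_identical(pick$seq[i],
                     substr(hg$seq, hstart + 1, hstart + nchar(pick$seq[i])))
  }

  expect_equal(nrow(simulate_short_reads(hap, ref, depth = 0)), 0)
  expect_error(simulate_short_reads(hap, ref, 10, read_len = 250L,
                                    frag_mean = 200), "frag_mean")
})

test_that("long-read simulation separates full-length and truncated molecules", {
  ref <- full_ref()
  h0 <- generate_haplotypes(ref, 0, 0, 0, seed = 1)[[1]]  # reference-equal

  # no truncation, no error: every read length equals its amplicon length
  lr <- simulate_long_reads(h0, ref, depth = 20,
                            profile = zero_error_profile(),
                            truncated_fraction = 0, seed = 5)
  validate_reads(lr, ref)
  expect_setequal(unique(nchar(lr$seq)), c(8300, 8600))

  # truncated molecules: forward strand, start at the amplicon primer,
  # lengths within [500, 4000]
  lr2 <- simulate_long_reads(h0, ref, depth = 30,
                             profile = zero_error_profile(),
                             truncated_fraction = 0.5, seed = 6)
  short <- lr2[nchar(lr2$seq) < 8000, ]
  expect_gt(nrow(short), 0)
  expect_true(all(short$strand == "+"))
  expect_true(all(short$ref_start %in% ref$amplicons$start))
  expect_true(all(nchar(short$seq) >= 500 & nchar(short$seq) <= 4000))

  expect_error(simulate_long_reads(h0, ref, 10, truncated_fraction = 1.5),
               "truncated_fraction")
})

test_that("homopolymer runs attract extra deletions (Monte-Carlo oracle)", {
  ref <- full_ref()
  h0 <- generate_haplotypes(ref, 0, 0, 0, seed = 1)[[1]]
  prof <- error_profile(deletion = 0.02, homopolymer_extra_deletion = 0.5)
  lr <- simulate_long_reads(h0, ref, depth = 700,
                            profile = prof, truncated_fraction = 0, seed = 9)
  p <- build_pileup(lr, ref)
  mask <- mitomix:::homopolymer_mask(ref)
  expect_gt(sum(p$depth[mask]), 1000)  # >= 1000 simulated run traversals
  rate_in <- sum(p$del[mask]) / sum(p$depth[mask])
  rate_out <- sum(p$del[!mask]) / sum(p$depth[!mask])
  # inside runs the per-base deletion probability is 0.52 vs 0.02 outside
  expect_gt(rate_in, rate_out + 0.3)
  expect_lt(abs(rate_out - 0.02), 0.01)
})

test_that("mixture ratios shape private-variant allele fractions", {
  ref <- tiny_ref()
  h <- tiny_haps()
  deep <- simulate_mixture(h[[1]], h[[2]], ref, c(0.5, 0.5),
                           short_depth = 3000, long_depth = 0,
                           short_profile = zero_error_profile(),
                           read_len = 100L, frag_mean = 200, frag_sd = 20,
                           seed = 41)
  p <- build_pileup(deep$short, ref)
  for (hap in h) {
    priv <- truth_snps(hap)
    priv <- priv[priv$pos %in% hap$private$pos, ]
    for (i in seq_len(nrow(priv))) {
      col <- pileup_column(p, priv$pos[i])
      expect_lt(abs(vaf(col, priv$alt[i]) - 0.5), 0.03)
    }
  }
  sh <- h[[1]]$shared
  for (i in seq_len(nrow(sh))) {
    expect_gt(vaf(pileup_column(p, sh$pos[i]), sh$alt[i]), 0.999)
  }

  # uneven ratio: private fractions near the molecule proportions, within
  # binomial error at the observed site depth
  mix73 <- simulate_mixture(h[[1]], h[[2]], ref, c(0.7, 0.3),
                            short_depth = 3000, long_depth = 0,
                            short_profile = zero_error_profile(),
                            read_len = 100L, frag_mean = 200, frag_sd = 20,
                            seed = 43)
  p73 <- build_pileup(mix73$short, ref)
  for (k in 1:2) {
    expected <- c(0.7, 0.3)[k]
    priv <- h[[k]]$private[h[[k]]$private$vclass == "SNP", ]
    for (i in seq_len(nrow(priv))) {
      col <- pileup_column(p73, priv$pos[i])
      tol <- 4 * sqrt(expected * (1 - expected) / col$depth)
      expect_lt(abs(vaf(col, priv$alt[i]) - expected), tol)
    }
  }

  # 1:0 ratio: only contributor A molecules
  m10 <- simulate_mixture(h[[1]], h[[2]], ref, c(1, 0), short_depth = 30,
                          long_depth = 10, read_len = 100L,
                          frag_mean = 200, frag_sd = 20, seed = 45)
  expect_true(all(m10$short$contributor == h[[1]]$contributor_id))
  expect_true(all(m10$long$contributor == h[[1]]$contributor_id))

  expect_error(simulate_mixture(h[[1]], h[[2]], ref, c(0.6, 0.6)), "ratio")
})

test_that("simulation is deterministic and conserves coverage", {
  ref <- tiny_ref()
  hap <- tiny_haps()[[1]]
  r1 <- simulate_short_reads(hap, ref, 30, 100L, 200, 20, seed = 8)
  r2 <- simulate_short_reads(hap, ref, 30, 100L, 200, 20, seed = 8)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(r1, ref, f1); write_sam(r2, ref, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical SAM

  # coverage conservation: total depth equals total aligned reference span
  lr <- simulate_long_reads(hap, ref, 40, long_error_profile(), 0.3, seed = 12)
  span <- sum(vapply(parse_cigar(lr$cigar), function(p)
    sum(p$len[p$op %in% c("M", "D")]), integer(1)))
  expect_equal(sum(coverage_track(lr, ref)$depth), span)
})

test_that("SAM round-trips losslessly and agrees with an external reader", {
  ref <- tiny_ref()
  reads <- rbind(
    simulate_short_reads(tiny_haps()[[1]], ref, 10, 100L, 200, 20, seed = 2),
    simulate_long_reads(tiny_haps()[[1]], ref, 10,
                        long_error_profile(), 0.4, seed = 2))
  path <- tempfile(fileext = ".sam")
  write_sam(reads, ref, path)
  back <- read_sam(path)
  rownames(reads) <- rownames(back) <- NULL
  expect_identical(back, reads)

  skip_if_not_installed("Rsamtools")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  ord <- order(match(
    ifelse(is.na(reads$mate), reads$read_id, reads$pair_id), rec$qname))
  expect_equal(length(rec$pos), nrow(reads))
  expect_equal(sort(rec$pos), sort(reads$ref_start + 1L))
  expect_setequal(as.character(rec$cigar), unique(reads$cigar))
})
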