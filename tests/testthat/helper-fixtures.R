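# Shared fixtures, built lazily and cached for the whole test run.
# Small-genome fixtures (4 kb) exercise everything that does not depend on
# the 8 kb amplicon-spanning rule; phasing fixtures use the full-size genome.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_ref <- function() {
  fixture("tiny_ref", function() generate_reference(4000, 2, 6, seed = 11))
}

tiny_haps <- function() {
  fixture("tiny_haps", function()
    generate_haplotypes(tiny_ref(), n_shared = 5, n_private_snps_each = 3,
                        n_private_ins_each = 1, seed = 21))
}

full_ref <- function() {
  fixture("full_ref", function() generate_reference(16569, 3, 6, seed = 7))
}

full_haps <- function() {
  fixture("full_haps", function()
    generate_haplotypes(full_ref(), 31, 6, 1, seed = 1))
}

# zero-error tiny mixture at high depth (shared by pileup/deconvolution tests)
tiny_mixture_clean <- function() {
  fixture("tiny_mixture_clean", function() {
    h <- tiny_haps()
    simulate_mixture(h[[1]], h[[2]], tiny_ref(), c(0.5, 0.5),
                     short_depth = 400, long_depth = 0,
                     short_profile = zero_error_profile(),
                     read_len = 100L, frag_mean = 200, frag_sd = 20,
                     seed = 31)
  })
}

tiny_panel <- function() {
  fixture("tiny_panel", function() {
    h <- tiny_haps()
    private_variant_panel(
      combine_truth_sets(hap_variants(h[[1]]), hap_variants(h[[2]])))
  })
}

# hand-built read table for CIGAR-level unit cases
mk_reads <- function(ref_start, cigar, seq, contributor = "A",
                     platform = "SHORT", strand = "+", pair_id = NA_character_,
                     mate = NA_integer_, secondary = FALSE, mapped = TRUE,
                     read_id = NULL) {
  n <- length(cigar)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  data.frame(read_id = rep_len(read_id, n),
             contributor = rep_len(contributor, n),
             platform = rep_len(platform, n),
             ref_start = as.integer(rep_len(ref_start, n)),
             cigar = cigar, seq = seq,
             qual = strrep("D", nchar(seq)),
             strand = rep_len(strand, n),
             pair_id = rep_len(pair_id, n),
             mate = rep_len(mate, n),
             secondary = rep_len(secondary, n),
             mapped = rep_len(mapped, n), stringsAsFactors = FALSE)
}

# call-set data frame from position/alt vectors (for concordance tests)
mk_calls <- function(pos, alt) {
  data.frame(pos = as.integer(pos), alt = rep_len(alt, length(pos)),
             stringsAsFactors = FALSE)
}

# truth SNPs (positions + alts) of one haplotype
truth_snps <- function(hap) {
  v <- hap_variants(hap)
  v[v$vclass == "SNP", , drop = FALSE]
}
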