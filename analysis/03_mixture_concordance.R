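#!/usr/bin/env Rscript
# Stage 3 -- mixture concordance against the combined truth set.
#
# The 0.90-VAF single-source short-read call sets are merged into one
# combined truth set (shared vs private labels). The mixture short-read
# pileup is then thresholded over VAF 0.17..0.53 in steps of 0.02 against
# that single truth member; a 0.25 mixture call set is fixed and the
# mixture long-read pileup is scored against it over the same threshold
# range. In a 1:1 mixture a private SNP is carried by about half of the
# reads and a shared SNP by essentially all of them, which is why the
# mixture detection threshold has to sit well below the single-source one.

suppressPackageStartupMessages(library(mitomix))

run_dir <- "scratch/run"
stopifnot(dir.exists(run_dir))
dir.create("results", showWarnings = FALSE)

fa <- Biostrings::readDNAStringSet(file.path(run_dir, "reference.fasta"))
ref <- structure(list(name = names(fa)[1],
                      sequence = as.character(fa[[1]]),
                      length = Biostrings::width(fa)[1], circular = TRUE),
                 class = "mito_reference")

calls <- lapply(c("A", "B"), function(id) {
  short <- read_sam(file.path(run_dir, paste0("single_", id, "_short.sam")))
  call_snps(build_pileup(short, ref), ref, 0.90, 20, "single_source")
})
combined <- combine_truth_sets(calls[[1]], calls[[2]])
cat(sprintf("combined truth set: %d shared + %d private SNPs\n",
            attr(combined, "n_shared"), attr(combined, "n_private")))
write.table(combined, "results/combined_truth_set.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mix_short <- build_pileup(read_sam(file.path(run_dir, "mixture_short.sam")), ref)
mix_long <- build_pileup(read_sam(file.path(run_dir, "mixture_long.sam")), ref)

g_short <- vaf_grid(mix_short, NULL, ref, test_range = c(0.17, 0.53, 0.02),
                    ploidy_mode = "mixture", truth_calls = combined)
write_grid(g_short, "results/mixture_short_f1_matrix.tsv",
           "results/mixture_short_grid.tsv")
cat(sprintf("mixture short vs combined truth: max F1 %.3f at test VAF %s\n",
            max(g_short$argmax_cells$f1),
            paste(range(g_short$argmax_cells$test_vaf), collapse = "-")))

mix_025 <- call_snps(mix_short, ref, 0.25, 20, "mixture")
g_long <- vaf_grid(mix_long, NULL, ref, test_range = c(0.17, 0.53, 0.02),
                   ploidy_mode = "mixture", truth_calls = mix_025)
write_grid(g_long, "results/mixture_long_f1_matrix.tsv",
           "results/mixture_long_grid.tsv")
best <- g_long$argmax_cells
cat(sprintf("mixture long vs short-0.25 truth: max F1 %.3f at long VAF %s\n",
            max(best$f1), paste(range(best$test_vaf), collapse = "-")))
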