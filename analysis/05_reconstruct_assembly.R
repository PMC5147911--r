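#!/usr/bin/env Rscript
# Stage 5 -- per-contributor consensus reconstruction and assembly stats.
#
# Each contributor's phased long reads and deconvolved short reads are
# merged into one pileup; every alternate signal reaching VAF 0.75 is
# applied to the reference, and the supporting call set is classified
# against that contributor's truth variants. Nx and NGAx curves summarise
# the reconstructed contigs.

suppressPackageStartupMessages(library(mitomix))

run_dir <- "scratch/run"
stopifnot(dir.exists(run_dir))
dir.create("results", showWarnings = FALSE)

fa <- Biostrings::readDNAStringSet(file.path(run_dir, "reference.fasta"))
ref <- structure(list(name = names(fa)[1],
                      sequence = as.character(fa[[1]]),
                      length = Biostrings::width(fa)[1], circular = TRUE),
                 class = "mito_reference")
truth <- read_truth_table(file.path(run_dir, "truth_variants.tsv"))

rows <- list()
curves <- list()
for (id in c("A", "B")) {
  phased <- read_sam(file.path(run_dir, paste0("phased_", id, ".sam")))
  dec <- read_sam(file.path(run_dir, paste0("deconvolved_", id, ".sam")))
  tv <- truth[truth$sharing %in% c("shared", paste0("private:", id)),
              c("pos", "ref", "alt")]
  cons <- reconstruct_contributor(phased, dec, ref, vaf = 0.75, truth = tv,
                                  contributor_id = id)
  print(cons)
  nx <- nx_curve(cons$contig_lengths)
  ngax <- ngax_curve(cons$contig_lengths, ref$length)
  rows[[id]] <- data.frame(
    contributor = id, consensus_bp = nchar(cons$sequence),
    n_contigs = length(cons$contig_lengths), n_gaps = length(cons$gaps),
    calls = nrow(cons$calls), tp = cons$concordance$tp,
    fp = cons$concordance$fp, fn = cons$concordance$fn,
    f1 = round(cons$concordance$f1, 3),
    n50 = unname(nx$n50), nga50 = unname(ngax$nga50))
  curves[[id]] <- data.frame(contributor = id, x = 1:100,
                             nx = unname(nx$nx), ngax = unname(ngax$ngax))
}
write.table(do.call(rbind, rows), "results/reconstruction_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, curves), "results/assembly_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(do.call(rbind, rows), row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dat <- do.call(rbind, curves)
  long <- rbind(data.frame(dat[c("contributor", "x")], stat = "Nx",
                           kb = dat$nx / 1000),
                data.frame(dat[c("contributor", "x")], stat = "NGAx",
                           kb = dat$ngax / 1000))
  pl <- ggplot(long, aes(x, kb, colour = contributor)) +
    geom_step() + facet_wrap(~stat) +
    labs(x = "x (% of total / genome)", y = "contig size (kb)") +
    theme_minimal()
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/assembly_curves.png", pl,
         width = 7, height = 3.5, dpi = 120)
}
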