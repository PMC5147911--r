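## End-to-end orchestration: simulate -> call -> grid -> phase ->
## deconvolve -> reconstruct, with every stochastic stage seeded
## deterministically from one global seed and (optionally) all primary
## outputs written to disk with a JSON manifest of digests.

#' Default pipeline configuration
#'
#' The defaults are the study conditions: a 16,569 bp circular genome with
#' three planted homopolymer runs, 31 shared + 2 x 6 private SNPs + 2 x 1
#' private insertions, a 1:1 mixture, a 1000x low-error paired short-read
#' platform and a 300x high-error long-read platform with 30% truncated
#' molecules, single-source grids over VAF 0.05..0.95 step 0.05, mixture
#' grids over 0.17..0.53 step 0.02, a truth VAF of 0.90, a mixture VAF of
#' 0.25, phasing intervals (1000, 8000) and (10000, 15000) with an 8000-base
#' query-length floor, and a reconstruction VAF of 0.75.
#'
#' @param seed global integer seed.
#' @param ... overrides for any config entry.
#' @return A `mito_config` list.
#' @export
pipeline_config <- function(seed = DEFAULT_SEED, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = 16569L,
    n_homopolymers = 3L,
    min_run = 6L,
    n_shared = 31L,
    n_private_snps_each = 6L,
    n_private_ins_each = 1L,
    contributors = c("A", "B"),
    mixture_ratio = c(0.5, 0.5),
    short_depth = 1000,
    long_depth = 300,
    read_len = 250L,
    frag_mean = 450,
    frag_sd = 50,
    truncated_fraction = 0.3,
    short_profile = short_error_profile(),
    long_profile = long_error_profile(),
    min_depth = 20L,
    single_grid = c(0.05, 0.95, 0.05),
    mixture_grid = c(0.17, 0.53, 0.02),
    truth_vaf = 0.90,
    mixture_vaf = 0.25,
    phasing_intervals = list(c(1000L, 8000L), c(10000L, 15000L)),
    min_query_len = 8000L,
    reconstruction_vaf = 0.75,
    outdir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_config("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "mito_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "mito_config"))
  if (abs(sum(cfg$mixture_ratio) - 1) > 1e-8)
    stop_config("mixture_ratio must sum to 1")
  if (cfg$frag_mean < cfg$read_len)
    stop_config("frag_mean must be >= read_len")
  if (cfg$truncated_fraction < 0 || cfg$truncated_fraction > 1)
    stop_config("truncated_fraction must lie in [0, 1]")
  if (!is.null(cfg$outdir) && !dir.exists(dirname(cfg$outdir)))
    stop_config("outdir parent does not exist: ", cfg$outdir)
  invisible(TRUE)
}

#' Run the full mixture-analysis pipeline
#'
#' Executes simulation, single-source calling and concordance grids, the
#' mixture grids against the combined 0.90-VAF truth set, long-read phasing,
#' short-read deconvolution, and per-contributor consensus reconstruction.
#' Re-running with the same config reproduces byte-identical primary
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return A `mito_run` list holding every stage's objects plus a `manifest`
#'   (seeds, parameters, file digests when `outdir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  cfg <- config
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    stage_times[[name]] <<- proc.time()[["elapsed"]] - t0
  }

  ## --- simulate -----------------------------------------------------------
  ref <- generate_reference(cfg$genome_length, cfg$n_homopolymers,
                            cfg$min_run, seed = derive_seed(cfg$seed, 1L))
  haps <- generate_haplotypes(ref, cfg$n_shared, cfg$n_private_snps_each,
                              cfg$n_private_ins_each,
                              seed = derive_seed(cfg$seed, 2L),
                              ids = cfg$contributors)
  singles <- lapply(1:2, function(i) {
    list(short = simulate_short_reads(haps[[i]], ref, cfg$short_depth,
                                      cfg$read_len, cfg$frag_mean, cfg$frag_sd,
                                      cfg$short_profile,
                                      seed = derive_seed(cfg$seed, 2L + i)),
         long = simulate_long_reads(haps[[i]], ref, cfg$long_depth,
                                    cfg$long_profile, cfg$truncated_fraction,
                                    seed = derive_seed(cfg$seed, 4L + i)))
  })
  mixture <- simulate_mixture(haps[[1]], haps[[2]], ref, cfg$mixture_ratio,
                              cfg$short_depth, cfg$long_depth,
                              cfg$short_profile, cfg$long_profile,
                              cfg$truncated_fraction, cfg$read_len,
                              cfg$frag_mean, cfg$frag_sd,
                              seed = derive_seed(cfg$seed, 7L))
  tick("simulate")

  ## --- single-source calling and grids ------------------------------------
  single_pileups <- lapply(singles, function(s)
    list(short = build_pileup(s$short, ref), long = build_pileup(s$long, ref)))
  truth_calls <- lapply(single_pileups, function(p)
    call_snps(p$short, ref, cfg$truth_vaf, cfg$min_depth, "single_source"))
  single_grids <- lapply(single_pileups, function(p)
    vaf_grid(p$long, p$short, ref, cfg$single_grid, cfg$single_grid,
             "single_source", cfg$min_depth))
  tick("single_source")

  ## --- mixture truth and grids --------------------------------------------
  combined_truth <- combine_truth_sets(truth_calls[[1]], truth_calls[[2]],
                                       labels = cfg$contributors)
  mix_pileups <- list(short = build_pileup(mixture$short, ref),
                      long = build_pileup(mixture$long, ref))
  ## short mixture thresholds against the combined single-source truth
  mix_short_grid <- vaf_grid(mix_pileups$short, NULL, ref,
                             test_range = cfg$mixture_grid,
                             truth_range = NULL,
                             ploidy_mode = "mixture", min_depth = cfg$min_depth,
                             truth_calls = combined_truth)
  mix_calls_short <- call_snps(mix_pileups$short, ref, cfg$mixture_vaf,
                               cfg$min_depth, "mixture")
  mix_long_grid <- vaf_grid(mix_pileups$long, NULL, ref,
                            test_range = cfg$mixture_grid,
                            truth_range = NULL,
                            ploidy_mode = "mixture", min_depth = cfg$min_depth,
                            truth_calls = mix_calls_short)
  tick("mixture_grids")

  ## --- phasing -------------------------------------------------------------
  truth_combined_full <- combine_truth_sets(hap_variants(haps[[1]]),
                                            hap_variants(haps[[2]]),
                                            labels = cfg$contributors)
  panel <- private_variant_panel(truth_combined_full, cfg$contributors)
  het_sites <- panel$snps
  spanning <- extract_spanning_reads(mixture$long, cfg$phasing_intervals,
                                     cfg$min_query_len)
  partitions <- lapply(spanning, phase_reads, het_sites = het_sites)
  phased <- list(
    A = do.call(rbind, lapply(partitions, `[[`, "pool_A")),
    B = do.call(rbind, lapply(partitions, `[[`, "pool_B")))
  tick("phasing")

  ## --- deconvolution --------------------------------------------------------
  assignment <- deconvolve(mixture$short, panel)
  deconvolved <- build_deconvolved_sets(assignment)
  tick("deconvolution")

  ## --- reconstruction -------------------------------------------------------
  consensus <- lapply(1:2, function(i) {
    id <- cfg$contributors[i]
    reconstruct_contributor(phased[[id]], deconvolved[[id]], ref,
                            vaf = cfg$reconstruction_vaf,
                            min_depth = cfg$min_depth,
                            truth = hap_variants(haps[[i]]),
                            contributor_id = id)
  })
  names(consensus) <- cfg$contributors
  assembly <- lapply(consensus, function(cs) {
    list(nx = nx_curve(cs$contig_lengths),
         ngax = ngax_curve(cs$contig_lengths, ref$length))
  })
  coverage <- list(
    mixture_short = coverage_track(mixture$short, ref),
    mixture_long = coverage_track(mixture$long, ref))
  tick("reconstruct")

  run <- structure(list(
    config = cfg, ref = ref, haps = haps, singles = singles,
    mixture = mixture, single_pileups = single_pileups,
    truth_calls = truth_calls, single_grids = single_grids,
    combined_truth = combined_truth, mix_pileups = mix_pileups,
    mix_short_grid = mix_short_grid, mix_calls_short = mix_calls_short,
    mix_long_grid = mix_long_grid, panel = panel, partitions = partitions,
    phased = phased, assignment = assignment, deconvolved = deconvolved,
    consensus = consensus, assembly = assembly, coverage = coverage,
    stage_seconds = unlist(stage_times),
    manifest = NULL), class = "mito_run")

  if (!is.null(cfg$outdir)) run <- write_run(run, cfg$outdir)
  run
}

#' @export
print.mito_run <- function(x, ...) {
  cat("mito_run: seed ", x$config$seed, "; ",
      nrow(x$mixture$short), " mixture short reads, ",
      nrow(x$mixture$long), " mixture long reads\n", sep = "")
  invisible(x)
}

#' Write a pipeline run's primary outputs and manifest
#'
#' @param run a `mito_run`.
#' @param outdir output directory (created if needed).
#' @return The run, with `manifest` filled in.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  p <- function(...) file.path(outdir, paste0(...))
  write_reference_fasta(run$ref, p("reference.fasta"))
  write_truth_table(run$haps, run$ref, p("truth_variants.tsv"))
  ids <- cfg$contributors
  for (i in 1:2) {
    write_sam(run$singles[[i]]$short, run$ref, p("single_", ids[i], "_short.sam"))
    write_sam(run$singles[[i]]$long, run$ref, p("single_", ids[i], "_long.sam"))
    write_calls(run$truth_calls[[i]], run$ref, p("calls_", ids[i], "_truthvaf.tsv"))
    write_grid(run$single_grids[[i]], p("grid_single_", ids[i], "_f1.tsv"),
               p("grid_single_", ids[i], "_long.tsv"))
  }
  write_sam(run$mixture$short, run$ref, p("mixture_short.sam"))
  write_sam(run$mixture$long, run$ref, p("mixture_long.sam"))
  write_grid(run$mix_short_grid, p("grid_mixture_short_f1.tsv"),
             p("grid_mixture_short.tsv"))
  write_grid(run$mix_long_grid, p("grid_mixture_long_f1.tsv"),
             p("grid_mixture_long.tsv"))
  for (id in ids) {
    write_sam(run$phased[[id]], run$ref, p("phased_", id, ".sam"))
    write_sam(run$deconvolved[[id]], run$ref, p("deconvolved_", id, ".sam"))
    export_fastq(run$deconvolved[[id]], p("deconvolved_", id, "_R1.fastq"),
                 p("deconvolved_", id, "_R2.fastq"))
    write_consensus_fasta(run$consensus[[id]], p("consensus_", id, ".fasta"))
    write_calls(run$consensus[[id]]$calls, run$ref, p("consensus_", id, "_calls.tsv"))
  }
  write_bedgraph(run$coverage$mixture_short$depth, run$ref,
                 p("coverage_mixture_short.bedgraph"))
  write_bedgraph(run$coverage$mixture_long$depth, run$ref,
                 p("coverage_mixture_long.bedgraph"))

  files <- sort(list.files(outdir, full.names = TRUE))
  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("short_profile", "long_profile",
                                           "phasing_intervals", "outdir"))],
    error_profiles = list(short = unclass(cfg$short_profile),
                          long = unclass(cfg$long_profile)),
    rotation = run$ref$rotation,
    amplicons = run$ref$amplicons,
    stage_seconds = round(run$stage_seconds, 2),
    digests = setNames(as.list(unname(tools::md5sum(files))), basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run$manifest <- manifest
  run
}
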