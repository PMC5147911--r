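## Call-set concordance: recall, precision and F1 over VAF threshold grids.
##
## Sites are matched by (position, alternate allele); a correct-position,
## wrong-allele call therefore counts as one false positive plus one false
## negative. Metrics with a zero denominator are reported as NA (undefined),
## never silently 0; F1 is 0 when tp = 0 with fp + fn > 0.

#' Classify a test call set against a truth call set
#'
#' A site keyed by (position, alt) is a true positive if present in both
#' sets, a false negative if present in truth only, a false positive if
#' present in test only. Recall is tp/(tp+fn), precision tp/(tp+fp), F1 the
#' harmonic mean of the two.
#'
#' @param test,truth call data frames with `pos` and `alt` columns.
#' @return A `mito_concordance` list: site key vectors `tp_sites`,
#'   `fp_sites`, `fn_sites`; counts `tp`, `fp`, `fn`; `recall`, `precision`,
#'   `f1` (NA when undefined).
#' @export
classify <- function(test, truth) {
  test_keys <- unique(variant_key(test$pos, test$alt))
  truth_keys <- unique(variant_key(truth$pos, truth$alt))
  tp_sites <- intersect(test_keys, truth_keys)
  fp_sites <- setdiff(test_keys, truth_keys)
  fn_sites <- setdiff(truth_keys, test_keys)
  concordance_from_counts(length(tp_sites), length(fp_sites), length(fn_sites),
                          tp_sites, fp_sites, fn_sites)
}

#' Concordance metrics from confusion counts
#'
#' @param tp,fp,fn non-negative counts.
#' @param tp_sites,fp_sites,fn_sites optional site key vectors.
#' @return A `mito_concordance` list.
#' @export
concordance_from_counts <- function(tp, fp, fn, tp_sites = NULL,
                                    fp_sites = NULL, fn_sites = NULL) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall)
        else if (fp + fn > 0) 0 else NA_real_
  structure(list(tp_sites = tp_sites, fp_sites = fp_sites, fn_sites = fn_sites,
                 tp = tp, fp = fp, fn = fn,
                 recall = recall, precision = precision, f1 = f1),
            class = "mito_concordance")
}

#' @export
print.mito_concordance <- function(x, ...) {
  cat(sprintf("TP: %d, FP: %d, FN: %d | recall %s, precision %s, F1 %s\n",
              x$tp, x$fp, x$fn,
              format(round_metric(x$recall)), format(round_metric(x$precision)),
              format(round_metric(x$f1))))
  invisible(x)
}

#' Enumerate VAF thresholds of a grid axis
#'
#' @param lo,hi inclusive bounds.
#' @param step positive increment.
#' @return Numeric thresholds `lo, lo+step, ..., hi` (floating-point safe).
#' @export
vaf_thresholds <- function(lo, hi, step) {
  if (step <= 0) stop_config("step must be positive")
  n <- floor((hi - lo) / step + 1e-9)
  thr <- round(lo + step * (0:n), 10)
  if (!length(thr)) stop_config("threshold range produced no thresholds")
  thr
}

#' Concordance grid over VAF threshold pairs
#'
#' Calls SNPs from the truth-axis pileup at every threshold of
#' `truth_range` and from the test-axis pileup at every threshold of
#' `test_range`, classifying every (truth, test) pair. Cells attaining the
#' maximum F1 are listed in row-major (truth ascending, then test ascending)
#' order; ties are all reported.
#'
#' @param test_pileup,truth_pileup `mito_pileup`s (`truth_pileup` may be
#'   NULL when `truth_calls` is given).
#' @param ref the reference genome.
#' @param test_range,truth_range `c(lo, hi, step)` threshold ranges (use
#'   `lo == hi` for a single-member axis; `truth_range` is ignored when
#'   `truth_calls` is given).
#' @param ploidy_mode passed to [call_snps()].
#' @param min_depth passed to [call_snps()].
#' @param truth_calls optional fixed truth call set: the truth axis then has
#'   this single member (as when a combined single-source truth set is
#'   compared against a range of mixture thresholds).
#' @return A `mito_grid`: threshold vectors, long-format `cells` data frame
#'   (truth_vaf, test_vaf, tp, fp, fn, recall, precision, f1), an `f1`
#'   matrix (truth x test), and `argmax_cells`.
#' @export
vaf_grid <- function(test_pileup, truth_pileup, ref,
                     test_range = c(0.05, 0.95, 0.05),
                     truth_range = c(0.05, 0.95, 0.05),
                     ploidy_mode = "single_source", min_depth = 20L,
                     truth_calls = NULL) {
  t_test <- vaf_thresholds(test_range[1], test_range[2], test_range[3])
  test_calls <- lapply(t_test, function(t)
    call_snps(test_pileup, ref, t, min_depth, ploidy_mode))
  if (is.null(truth_calls)) {
    t_truth <- vaf_thresholds(truth_range[1], truth_range[2], truth_range[3])
    truth_calls <- lapply(t_truth, function(t)
      call_snps(truth_pileup, ref, t, min_depth, ploidy_mode))
  } else {
    thr <- attr(truth_calls, "threshold")
    t_truth <- if (is.null(thr)) NA_real_ else thr
    truth_calls <- list(truth_calls)
  }

  rows <- vector("list", length(t_truth) * length(t_test))
  f1m <- matrix(NA_real_, length(t_truth), length(t_test),
                dimnames = list(format(t_truth), format(t_test)))
  k <- 0L
  for (i in seq_along(t_truth)) {
    for (j in seq_along(t_test)) {
      cc <- classify(test_calls[[j]], truth_calls[[i]])
      k <- k + 1L
      rows[[k]] <- data.frame(truth_vaf = t_truth[i], test_vaf = t_test[j],
                              tp = cc$tp, fp = cc$fp, fn = cc$fn,
                              recall = cc$recall, precision = cc$precision,
                              f1 = cc$f1)
      f1m[i, j] <- cc$f1
    }
  }
  cells <- do.call(rbind, rows)
  argmax <- cells[!is.na(cells$f1) & cells$f1 == max(cells$f1, na.rm = TRUE),
                  c("truth_vaf", "test_vaf", "f1"), drop = FALSE]
  rownames(argmax) <- NULL
  structure(list(truth_thresholds = t_truth, test_thresholds = t_test,
                 cells = cells, f1 = f1m, argmax_cells = argmax),
            class = "mito_grid")
}

#' @export
print.mito_grid <- function(x, ...) {
  cat("mito_grid: ", length(x$truth_thresholds), " truth x ",
      length(x$test_thresholds), " test thresholds; max F1 ",
      format(round_metric(max(x$f1, na.rm = TRUE))), " at ",
      nrow(x$argmax_cells), " cell(s)\n", sep = "")
  invisible(x)
}

#' Write a grid as a tab-separated F1 matrix and a long-format table
#' @param grid a `mito_grid`.
#' @param matrix_path,long_path output files (either may be NULL to skip).
#' @return Invisibly, the grid.
#' @export
write_grid <- function(grid, matrix_path = NULL, long_path = NULL) {
  if (!is.null(matrix_path)) {
    write.table(round(grid$f1, 3), matrix_path, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  if (!is.null(long_path)) {
    cells <- grid$cells
    cells$recall <- round_metric(cells$recall)
    cells$precision <- round_metric(cells$precision)
    cells$f1 <- round_metric(cells$f1)
    write.table(cells, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(grid)
}

#' Combine two single-source call sets into a mixture truth set
#'
#' The union is keyed by (position, alt): entries present in both inputs
#' with the same alternate are labelled `shared`; entries present in exactly
#' one are labelled `private:<label>`. Same position with different
#' alternates yields two private entries.
#'
#' @param a,b call data frames.
#' @param labels length-2 labels for the two sources.
#' @return A `mito_truthset` data frame (`pos`, `alt`, `sharing`, plus `ref`
#'   and `vclass` when available) with counts in attributes `n_shared`,
#'   `n_private`.
#' @export
combine_truth_sets <- function(a, b, labels = c("A", "B")) {
  ka <- variant_key(a$pos, a$alt)
  kb <- variant_key(b$pos, b$alt)
  all_keys <- union(ka, kb)
  src <- rbind(
    data.frame(pos = a$pos, alt = a$alt,
               ref = if ("ref" %in% names(a)) a$ref else NA_character_,
               vclass = if ("vclass" %in% names(a)) a$vclass else NA_character_,
               key = ka, stringsAsFactors = FALSE),
    data.frame(pos = b$pos, alt = b$alt,
               ref = if ("ref" %in% names(b)) b$ref else NA_character_,
               vclass = if ("vclass" %in% names(b)) b$vclass else NA_character_,
               key = kb, stringsAsFactors = FALSE))
  src <- src[!duplicated(src$key), , drop = FALSE]
  src <- src[match(all_keys, src$key), , drop = FALSE]
  sharing <- ifelse(all_keys %in% ka & all_keys %in% kb, "shared",
                    ifelse(all_keys %in% ka, paste0("private:", labels[1]),
                           paste0("private:", labels[2])))
  out <- data.frame(pos = src$pos, ref = src$ref, alt = src$alt,
                    vclass = src$vclass, sharing = sharing,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_shared = sum(sharing == "shared"),
            n_private = sum(sharing != "shared"),
            class = c("mito_truthset", "data.frame"))
}
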