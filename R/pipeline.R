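#' Pipeline configuration
#'
#' One structured configuration for the whole analysis chain; the generator
#' section is used when no spot table is supplied, so the pipeline is
#' runnable end-to-end on synthetic data.
#'
#' @param generator A [generator_config()] (ignored when `spot_table` and
#'   `design` paths are given).
#' @param spot_table,design_sheet Optional paths to an existing GPR-like
#'   spot TSV and design CSV.
#' @param snr_min,diameter_min,cv_max QC thresholds (see
#'   [validate_spots()]).
#' @param lowess_span,min_group Normalization settings (see
#'   [normalize_within_print_tip()]).
#' @param sd_min,r_threshold Classification thresholds (see
#'   [classify_steady_state()]).
#' @param null_draws,null_seed Null-calibration settings; `null_draws = 0`
#'   skips the null simulation.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   are written there as TSV/JSON.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            spot_table = NULL, design_sheet = NULL,
                            snr_min = 5, diameter_min = 75, cv_max = 1.0,
                            lowess_span = 0.4, min_group = 20,
                            sd_min = 0.21, r_threshold = 0.75,
                            null_draws = 0, null_seed = 1,
                            out_dir = NULL) {
  stopifnot(snr_min > 0, diameter_min > 0, cv_max > 0,
            lowess_span > 0, lowess_span <= 1,
            sd_min >= 0, r_threshold >= 0, r_threshold <= 1,
            null_draws >= 0)
  structure(list(
    generator = generator, spot_table = spot_table,
    design_sheet = design_sheet, snr_min = snr_min,
    diameter_min = diameter_min, cv_max = cv_max,
    lowess_span = lowess_span, min_group = min_group, sd_min = sd_min,
    r_threshold = r_threshold, null_draws = null_draws,
    null_seed = null_seed, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Generate (or load) spot data, filter defective spots, compute and
#' normalize log ratios within print-tip groups, average replicate spots,
#' estimate per-gene time-course contrasts over the loop design, and
#' classify steady-state responders; optionally calibrate the null. Returns
#' a run manifest of stage-by-stage record counts; with `out_dir` set, all
#' stage tables are written alongside the manifest.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest` (named counts and settings), `design`,
#'   `truth` (`NULL` for loaded data), `spots`, `filter_report`, `ratios`,
#'   `profiles`, `calls`, and `null` (a [simulate_null()] result or `NULL`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  truth <- NULL
  if (!is.null(config$spot_table)) {
    spots <- read_spot_table(config$spot_table)
    design <- read_design(config$design_sheet)
  } else {
    design <- default_loop_design()
    truth <- make_truth(config$generator)
    spots <- simulate_slides(truth, design, config$generator)
  }
  filt <- filter_spots(spots, config$snr_min, config$diameter_min,
                       config$cv_max)
  ratios <- compute_MA(filt$valid)
  ratios <- normalize_within_print_tip(ratios, span = config$lowess_span,
                                       min_group = config$min_group)
  slide_means <- average_replicates(ratios, "M_normalized")
  profiles <- estimate_profiles(slide_means, design)
  calls <- suppressMessages(
    classify_steady_state(profiles, sd_min = config$sd_min,
                          r_threshold = config$r_threshold)
  )
  null <- if (config$null_draws > 0) {
    simulate_null(config$null_draws, seed = config$null_seed)
  }
  manifest <- list(
    n_spots_in = filt$report$n_total,
    n_spots_valid = filt$report$n_valid,
    fraction_spots_valid = filt$report$fraction_valid,
    n_genes = length(unique(spots$gene_id)),
    n_genes_nonsingular = count_nonsingular(profiles),
    n_sd_filter_survivors = sum(calls$passed_sd_filter, na.rm = TRUE),
    n_class_up = sum(calls$label == "up"),
    n_class_down = sum(calls$label == "down"),
    sd_min = config$sd_min, r_threshold = config$r_threshold,
    seed = if (is.null(config$spot_table)) config$generator$seed else NA
  )
  res <- list(manifest = manifest, design = design, truth = truth,
              spots = spots, filter_report = filt$report, ratios = ratios,
              profiles = profiles, calls = calls, null = null)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_design(res$design, p("design.csv"))
  if (!is.null(res$truth)) write_truth_table(res$truth, p("truth.tsv"))
  write_spot_table(res$spots, p("spots.tsv"))
  utils::write.table(res$ratios, p("ratios_normalized.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_profiles(res$profiles, p("profiles.tsv"))
  utils::write.table(res$calls, p("calls.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$filter_report, p("filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(res$null)) {
    jsonlite::write_json(
      res$null[c("n_draws", "seed", "n", "mode", "density_at_zero",
                 "ks_distance", "tail_prob")],
      p("null_model.json"), auto_unbox = TRUE, digits = NA)
  }
  export_class_matrix(res$calls, res$profiles, p("class_matrix.tsv"))
  invisible(out_dir)
}

#' Export the classed profile matrix
#'
#' Emits the genes x time-points matrix of contrasts for the two
#' steady-state classes (up-then-relax first, then down-then-relax), each
#' block in gene-id order, with missing entries encoded as `NA` — the
#' tabular equivalent of the classed heat-map view of the results.
#'
#' @param calls Output of [classify_steady_state()].
#' @param profiles Matching [estimate_profiles()] output.
#' @param path Optional file path to write TSV; `NULL` returns the table
#'   only.
#' @return The `data.frame` (`class`, `gene_id`, `x1..x6`), invisibly when
#'   written.
#' @export
export_class_matrix <- function(calls, profiles, path = NULL) {
  stopifnot(identical(calls$gene_id, profiles$gene_id))
  keep <- calls$label %in% c("up", "down")
  out <- data.frame(
    class = ifelse(calls$label == "up", "I_up", "II_down")[keep],
    gene_id = calls$gene_id[keep],
    profiles[keep, paste0("x", 1:6)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$class, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}
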