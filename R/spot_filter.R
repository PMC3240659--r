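#' Spot validity flags
#'
#' Applies the three spot-validity criteria, per spot, with strict
#' inequalities: signal-to-noise ratio (foreground minus background, divided
#' by the background SD) greater than `snr_min` in both channels; spot
#' diameter greater than `diameter_min` micrometres; pixel coefficient of
#' variation less than `cv_max` in both channels. A zero background SD makes
#' the SNR infinite when the foreground exceeds the background (the clean
#' synthetic limit) and invalid otherwise, flagged separately.
#'
#' @param spots Spot table with the GPR-like columns of
#'   [simulate_slides()].
#' @param snr_min SNR threshold (default 5).
#' @param diameter_min Minimum diameter in micrometres (default 75).
#' @param cv_max Maximum pixel CV as a fraction (default 1.0, i.e. 100%).
#' @return A `data.frame` of logical flags `pass_snr`, `pass_diameter`,
#'   `pass_cv`, `snr_undefined`, and `valid` (the conjunction), one row per
#'   spot.
#' @export
validate_spots <- function(spots, snr_min = 5, diameter_min = 75,
                           cv_max = 1.0) {
  snr <- function(fg, bg, bsd) {
    s <- (fg - bg) / bsd
    s[bsd == 0] <- ifelse(fg[bsd == 0] > bg[bsd == 0], Inf, NaN)
    s
  }
  snr5 <- snr(spots$f635_mean, spots$b635_mean, spots$b635_sd)
  snr3 <- snr(spots$f532_mean, spots$b532_mean, spots$b532_sd)
  undef <- is.nan(snr5) | is.nan(snr3)
  pass_snr <- !undef & snr5 > snr_min & snr3 > snr_min
  pass_diameter <- spots$diameter_um > diameter_min
  pass_cv <- spots$cv635 < cv_max & spots$cv532 < cv_max
  data.frame(
    pass_snr = pass_snr, pass_diameter = pass_diameter, pass_cv = pass_cv,
    snr_undefined = undef,
    valid = pass_snr & pass_diameter & pass_cv
  )
}

#' Filter a spot table and report survival
#'
#' @inheritParams validate_spots
#' @return A list with `valid` (the surviving subset of `spots`) and
#'   `report`, a list with `n_total`, `n_valid`, `fraction_valid` (`NA` when
#'   `n_total` is 0), and per-criterion failure counts (`n_fail_snr`,
#'   `n_fail_diameter`, `n_fail_cv`; a spot may fail several).
#' @examples
#' cfg <- generator_config(n_genes = c(flat = 20), seed = 7)
#' spots <- simulate_slides(make_truth(cfg), default_loop_design(), cfg)
#' filter_spots(spots)$report$fraction_valid
#' @export
filter_spots <- function(spots, snr_min = 5, diameter_min = 75,
                         cv_max = 1.0) {
  flags <- validate_spots(spots, snr_min, diameter_min, cv_max)
  n_total <- nrow(spots)
  n_valid <- sum(flags$valid)
  report <- list(
    n_total = n_total,
    n_valid = n_valid,
    fraction_valid = if (n_total > 0) n_valid / n_total else NA_real_,
    n_fail_snr = sum(!flags$pass_snr),
    n_fail_diameter = sum(!flags$pass_diameter),
    n_fail_cv = sum(!flags$pass_cv),
    n_snr_undefined = sum(flags$snr_undefined)
  )
  list(valid = spots[flags$valid, , drop = FALSE], report = report)
}
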