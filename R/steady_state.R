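#' Ideal steady-state pattern
#'
#' The template for a perturbation-then-relaxation response over six time
#' points: v = (r, s, r, s, r, s), where r is the level 30 minutes after a
#' dose and s the relaxed level 8 hours after. The two values are arbitrary
#' (the correlation with the template is invariant to their affine rescaling)
#' but must differ; only sign(r - s) matters.
#'
#' @param r Response level.
#' @param s Steady-state (relaxed) level.
#' @return Numeric 6-vector (r, s, r, s, r, s).
#' @export
ideal_pattern <- function(r = 1, s = 0) {
  if (r == s) stop("pattern levels r and s must differ")
  rep(c(r, s), 3)
}

#' Standard deviation of an expression profile
#'
#' Sample standard deviation (n - 1 denominator) of the six contrasts; used
#' as the variability filter ahead of template scoring.
#'
#' @param x Numeric 6-vector of contrasts.
#' @return Scalar SD, or `NA` if any entry is missing.
#' @export
profile_sd <- function(x) {
  if (length(x) != 6) stop("profile must have 6 entries")
  if (anyNA(x)) return(NA_real_)
  stats::sd(x)
}

# population-convention SD (n denominator); zero-safe
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Template-correlation statistic R
#'
#' Pearson correlation between a profile x and the ideal pattern v. Because
#' v takes exactly two alternating values, the correlation reduces in closed
#' form to
#'   R = (mean(x[odd]) - mean(x[even])) / (2 * SD_pop(x))
#' for r > s (sign flipped for r < s), where SD_pop uses the n-denominator
#' convention; the reduction is exact and is cross-checked against the
#' direct Pearson computation in the test suite. R is in [-1, 1]; |R|
#' measures similarity to the perturbation-then-relaxation shape, with
#' R > 0 the up-then-relax orientation and R < 0 the mirrored one.
#'
#' @param x Numeric 6-vector (complete, non-constant).
#' @param pattern Ideal pattern from [ideal_pattern()]; only sign(r - s) has
#'   any effect.
#' @param method `"closed_form"` (default) or `"pearson"` (direct Eq-style
#'   correlation, used for cross-checks).
#' @return Scalar R in [-1, 1]; `NA` if the profile is incomplete or has
#'   zero variance.
#' @export
steady_state_R <- function(x, pattern = ideal_pattern(),
                           method = c("closed_form", "pearson")) {
  method <- match.arg(method)
  if (length(x) != 6) stop("profile must have 6 entries")
  if (anyNA(x)) return(NA_real_)
  s <- sd_pop(x)
  if (s == 0) return(NA_real_)
  sgn <- sign(pattern[1] - pattern[2])
  if (method == "pearson") {
    return(stats::cor(x, pattern))
  }
  sgn * (mean(x[c(1, 3, 5)]) - mean(x[c(2, 4, 6)])) / (2 * s)
}

# vectorized closed form over rows of a matrix (n columns, alternating
# template of length n); used by the null simulator
row_R <- function(X) {
  n <- ncol(X)
  odd <- seq(1, n, by = 2)
  even <- seq(2, n, by = 2)
  ctr <- X - rowMeans(X)
  sp <- sqrt(rowMeans(ctr^2))
  v <- rep(c(1, 0), length.out = n)
  vc <- v - mean(v)
  num <- (ctr %*% vc) / n
  as.vector(num / (sp * sd_pop(v)))
}

#' Analytic null density of R
#'
#' For a profile of n independent, identically distributed Gaussian entries,
#' the correlation with any fixed non-constant template has density
#' proportional to (1 - r^2)^((n-4)/2) on [-1, 1]; the normalizing constant
#' is the closed-form integral B(1/2, (n-2)/2) (a beta function). For the
#' six-point design this is exactly f(r) = 0.75 (1 - r^2).
#'
#' @param r Correlation value(s) in [-1, 1].
#' @param n Profile length (default 6).
#' @return Density value(s).
#' @export
analytic_null_density <- function(r, n = 6) {
  if (any(abs(r) > 1)) stop("density is supported on [-1, 1]")
  if (n < 3) stop("profile length must be at least 3")
  const <- 1 / beta(0.5, (n - 2) / 2)
  const * (1 - r^2)^((n - 4) / 2)
}

#' Analytic null CDF of R
#'
#' Uses the equivalent representation R^2 ~ Beta(1/2, (n - 2)/2) with R
#' symmetric about zero; for n = 6 this is the polynomial
#' 0.75 (r - r^3/3) + 1/2.
#'
#' @inheritParams analytic_null_density
#' @return Cumulative probability P(R <= r).
#' @export
analytic_null_cdf <- function(r, n = 6) {
  if (any(abs(r) > 1)) stop("CDF argument must be in [-1, 1]")
  0.5 + 0.5 * sign(r) * stats::pbeta(r^2, 0.5, (n - 2) / 2)
}

#' Simulate the null distribution of R
#'
#' Draws profiles under the null hypothesis of no structured response and
#' scores each against the ideal pattern. The default null draws n
#' independent standard-normal entries per profile; the permutation mode
#' instead permutes the entries of a supplied profile uniformly at random
#' (both nulls are exchangeable, so both converge to the same analytic
#' density).
#'
#' @param n_draws Number of simulated profiles (default one million).
#' @param seed Integer seed.
#' @param n Profile length (default 6).
#' @param mode `"normal"` or `"permutation"`.
#' @param profile Profile whose entries are permuted in permutation mode.
#' @return An object of class `null_model`: list with `draws`, `n_draws`,
#'   `seed`, `n`, `mode`, `density_at_zero` (empirical, window estimate),
#'   `ks_distance` (empirical vs analytic CDF), and `tail_prob` (empirical
#'   P(|R| > 0.75)).
#' @export
simulate_null <- function(n_draws = 1e6, seed = 1, n = 6,
                          mode = c("normal", "permutation"),
                          profile = NULL) {
  mode <- match.arg(mode)
  if (n_draws < 1) stop("n_draws must be at least 1")
  set.seed(seed)
  if (mode == "normal") {
    X <- matrix(stats::rnorm(n_draws * n), n_draws, n)
  } else {
    if (is.null(profile) || length(profile) != n || anyNA(profile)) {
      stop("permutation mode needs a complete profile of length n")
    }
    if (sd_pop(profile) == 0) stop("profile must be non-constant")
    X <- t(vapply(seq_len(n_draws),
                  function(i) profile[sample.int(n)], numeric(n)))
  }
  draws <- row_R(X)
  half <- 0.05
  dens0 <- mean(abs(draws) < half) / (2 * half)
  ks <- suppressWarnings(
    stats::ks.test(draws, function(q) analytic_null_cdf(q, n = n))$statistic
  )
  structure(list(
    draws = draws, n_draws = n_draws, seed = seed, n = n, mode = mode,
    density_at_zero = dens0, ks_distance = unname(ks),
    tail_prob = mean(abs(draws) > 0.75)
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "Null model of the template correlation R (n = %d, %s null)\n", x$n,
    x$mode))
  cat(sprintf("  draws: %d (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  density at R = 0: %.4f (analytic %.4f)\n",
              x$density_at_zero, analytic_null_density(0, x$n)))
  cat(sprintf("  KS distance to analytic CDF: %.5f\n", x$ks_distance))
  cat(sprintf("  P(|R| > 0.75): %.5f\n", x$tail_prob))
  invisible(x)
}

#' Classify expression profiles as steady-state responders
#'
#' The steady-state model-fitting decision: genes must first pass the
#' variability filter (sample SD of the six contrasts strictly greater than
#' `sd_min`); surviving genes with template correlation strictly above
#' `r_threshold` are called `up` (immediate up-regulation relaxing between
#' doses, class I), strictly below `-r_threshold` are called `down`
#' (class II), all others `none`. Singular or incomplete profiles are not
#' scored (the null density depends on the profile length, so shorter
#' profiles are not rescored against a truncated template).
#'
#' @param profiles Output of [estimate_profiles()].
#' @param sd_min Variability filter threshold (default 0.21, log2 units).
#' @param r_threshold Template-correlation threshold (default 0.75).
#' @param pattern Ideal pattern orientation.
#' @return A `data.frame`: `gene_id`, `sd`, `R`, `passed_sd_filter`,
#'   `label` (factor up/down/none), `scored` (FALSE for singular/incomplete
#'   profiles).
#' @export
classify_steady_state <- function(profiles, sd_min = 0.21,
                                  r_threshold = 0.75,
                                  pattern = ideal_pattern()) {
  xm <- as.matrix(profiles[, paste0("x", 1:6)])
  n <- nrow(xm)
  sdv <- Rv <- rep(NA_real_, n)
  label <- rep("none", n)
  scored <- rep(FALSE, n)
  for (i in seq_len(n)) {
    x <- xm[i, ]
    if (anyNA(x)) next
    sdv[i] <- profile_sd(x)
    scored[i] <- TRUE
    if (!(sdv[i] > sd_min)) next
    Rv[i] <- steady_state_R(x, pattern)
    if (is.na(Rv[i])) next
    if (Rv[i] > r_threshold) label[i] <- "up"
    else if (Rv[i] < -r_threshold) label[i] <- "down"
  }
  n_skipped <- sum(!scored)
  if (n_skipped > 0) {
    message(n_skipped, " singular/incomplete profile(s) not scored")
  }
  data.frame(
    gene_id = profiles$gene_id, sd = sdv, R = Rv,
    passed_sd_filter = !is.na(sdv) & sdv > sd_min,
    label = factor(label, levels = c("up", "down", "none")),
    scored = scored, stringsAsFactors = FALSE
  )
}

#' Directional consistency of a gene set over a time grid
#'
#' Counts time-point entries whose sign matches a direction across a set of
#' profiles (any grid length), e.g. to ask how consistently a class of
#' genes stays up-regulated under a different treatment. Exact zeros are
#' neither up nor down and are tallied separately.
#'
#' @param x Numeric matrix, genes x time points.
#' @param direction `"up"` (positive entries) or `"down"` (negative).
#' @return List with `n_matching`, `n_total` (non-missing entries),
#'   `n_zero`, and `fraction` (`NA` when no entries).
#' @export
directional_consistency <- function(x, direction = c("up", "down")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  vals <- x[!is.na(x)]
  n_total <- length(vals)
  n_match <- if (direction == "up") sum(vals > 0) else sum(vals < 0)
  list(
    n_matching = n_match, n_total = n_total, n_zero = sum(vals == 0),
    fraction = if (n_total > 0) n_match / n_total else NA_real_
  )
}

#' Cross-platform correlation
#'
#' Pearson correlation between paired measurements from two platforms
#' (e.g. microarray contrasts against quantitative PCR log fold changes),
#' used to validate the array pipeline against an independent assay.
#'
#' @param x_a,x_b Equal-length paired numeric vectors, at least 3 complete
#'   pairs, each with nonzero variance.
#' @return Pearson correlation, or `NA` (with a warning) when degenerate.
#' @export
crossplatform_correlation <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) stop("paired vectors must be equal length")
  ok <- !is.na(x_a) & !is.na(x_b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd_pop(x_a[ok]) == 0 || sd_pop(x_b[ok]) == 0) {
    warning("degenerate variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x_a[ok], x_b[ok])
}
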