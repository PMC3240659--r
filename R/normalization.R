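#' Log-ratio and mean-intensity values per spot
#'
#' Computes the standard two-channel summaries from background-corrected
#' intensities: M = log2(Cy5 - bg) - log2(Cy3 - bg) and A, their mean log2
#' intensity. Spots whose corrected intensity is non-positive in either
#' channel cannot be log-transformed and are dropped, with the number dropped
#' reported as an attribute.
#'
#' @param spots Spot table (normally the valid subset from
#'   [filter_spots()]).
#' @return A `data.frame` with `gene_id`, `slide_id`, `block`, `replicate`,
#'   `A`, `M`; attribute `n_dropped` counts spots removed for non-positive
#'   corrected intensity.
#' @export
compute_MA <- function(spots) {
  c5 <- spots$f635_mean - spots$b635_mean
  c3 <- spots$f532_mean - spots$b532_mean
  ok <- c5 > 0 & c3 > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " spot(s) dropped: non-positive background-corrected ",
            "intensity")
  }
  out <- data.frame(
    gene_id = spots$gene_id[ok], slide_id = spots$slide_id[ok],
    block = spots$block[ok], replicate = spots$replicate[ok],
    A = (log2(c5[ok]) + log2(c3[ok])) / 2,
    M = log2(c5[ok]) - log2(c3[ok]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Within-print-tip-group normalization
#'
#' Removes intensity-dependent and print-tip-specific bias from the log
#' ratios: within each (slide, block) group a robust local-regression trend
#' of M on A is fitted and subtracted. Groups smaller than `min_group` spots
#' cannot support a stable curve fit and are centred by their median M
#' instead. A never changes.
#'
#' @param ratios Output of [compute_MA()].
#' @param span Loess span (fraction of the group used per local fit).
#' @param iterations Robustness iterations of the loess fit.
#' @param min_group Minimum group size for curve fitting (median-centring
#'   below it).
#' @return The input with an added `M_normalized` column.
#' @export
normalize_within_print_tip <- function(ratios, span = 0.4, iterations = 4,
                                       min_group = 20) {
  if (nrow(ratios) == 0) {
    warning("no spots to normalize")
    ratios$M_normalized <- numeric(0)
    return(ratios)
  }
  key <- interaction(ratios$slide_id, ratios$block, drop = TRUE)
  mn <- ratios$M
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) >= min_group) {
      fit <- limma::loessFit(ratios$M[idx], ratios$A[idx], span = span,
                             iterations = iterations)
      mn[idx] <- ratios$M[idx] - fit$fitted
    } else {
      mn[idx] <- ratios$M[idx] - stats::median(ratios$M[idx])
    }
  }
  ratios$M_normalized <- mn
  ratios
}

#' Average replicate spots to one log ratio per gene per slide
#'
#' Replicate spots are normalized individually and then averaged, so QC
#' losses do not bias the normalization curve; the slide-level mean is the
#' response fed to the loop estimator.
#'
#' @param ratios Output of [normalize_within_print_tip()] (or
#'   [compute_MA()]; `column` selects which M to average).
#' @param column Name of the log-ratio column to average.
#' @return A `data.frame` with `gene_id`, `slide_id`, `m` (mean log ratio),
#'   `n_spots`.
#' @export
average_replicates <- function(ratios, column = "M_normalized") {
  if (!column %in% names(ratios)) {
    stop("no column '", column, "' in ratios")
  }
  agg <- stats::aggregate(
    ratios[[column]],
    by = list(gene_id = ratios$gene_id, slide_id = ratios$slide_id),
    FUN = mean
  )
  cnt <- stats::aggregate(
    ratios[[column]],
    by = list(gene_id = ratios$gene_id, slide_id = ratios$slide_id),
    FUN = length
  )
  out <- data.frame(gene_id = agg$gene_id, slide_id = agg$slide_id,
                    m = agg$x, n_spots = cnt$x, stringsAsFactors = FALSE)
  out[order(out$gene_id, out$slide_id), , drop = FALSE]
}
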