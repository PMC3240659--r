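#' Sample identifiers for the six-time-point perturbation series
#'
#' Twelve samples: controls C1..C6 and irradiated samples UV1..UV6, one pair
#' per sampling time point T1..T6. Odd time points are taken 30 minutes after
#' a dose (response), even time points 8 hours after (relaxation).
#'
#' @return Character vector of the 12 sample identifiers.
#' @export
loop_samples <- function() {
  c(paste0("C", 1:6), paste0("UV", 1:6))
}

#' Default 17-slide loop design
#'
#' Builds the default hybridization design: a closed 12-slide loop visiting
#' all 12 samples (C1 -> UV1 -> C2 -> UV2 -> ... -> C6 -> UV6 -> C1, with the
#' tail of each arrow labelled Cy3 and the head Cy5), two technical-replicate
#' slides (nos. 11 and 15), two dye-swap slides (nos. 14 and 16), and one
#' mock self-self slide (no. 17, C1 in both channels). Slides 1-10, 12 and 13
#' carry the loop. The mock slide is used for QC only and is excluded from
#' contrast estimation.
#'
#' @return A `data.frame` with one row per slide and columns `slide_id`
#'   (integer 1..17), `cy3_sample`, `cy5_sample`, and `role` (one of
#'   `"loop"`, `"technical_replicate"`, `"dye_swap"`, `"mock"`).
#' @examples
#' d <- default_loop_design()
#' table(d$role)
#' @export
default_loop_design <- function() {
  samples <- c(rbind(paste0("C", 1:6), paste0("UV", 1:6)))  # C1 UV1 C2 UV2 ...
  tails <- samples
  heads <- samples[c(2:12, 1)]
  # loop edges occupy slide numbers 1-10, 12, 13; 11/15 technical, 14/16 swap
  loop_ids <- c(1:10, 12, 13)
  design <- data.frame(
    slide_id = loop_ids,
    cy3_sample = tails,
    cy5_sample = heads,
    role = "loop",
    stringsAsFactors = FALSE
  )
  tech <- data.frame(
    slide_id = c(11L, 15L),
    cy3_sample = c(tails[10], tails[12]),
    cy5_sample = c(heads[10], heads[12]),
    role = "technical_replicate",
    stringsAsFactors = FALSE
  )
  swap <- data.frame(
    slide_id = c(14L, 16L),
    cy3_sample = c(heads[1], heads[2]),
    cy5_sample = c(tails[1], tails[2]),
    role = "dye_swap",
    stringsAsFactors = FALSE
  )
  mock <- data.frame(
    slide_id = 17L, cy3_sample = "C1", cy5_sample = "C1", role = "mock",
    stringsAsFactors = FALSE
  )
  out <- rbind(design, tech, swap, mock)
  out <- out[order(out$slide_id), ]
  rownames(out) <- NULL
  validate_loop_design(out)
  out
}

#' Validate a loop design table
#'
#' Checks structural soundness: required columns, known roles, mock slides
#' self-self, and connectivity of the non-mock slide graph (samples as nodes,
#' slides as edges) so that every contrast is estimable for a fully measured
#' gene.
#'
#' @param design A design `data.frame` as returned by [default_loop_design()]
#'   or read with [read_design()].
#' @return The design, invisibly; errors if invalid.
#' @export
validate_loop_design <- function(design) {
  needed <- c("slide_id", "cy3_sample", "cy5_sample", "role")
  if (!all(needed %in% names(design))) {
    stop("design must have columns: ", paste(needed, collapse = ", "))
  }
  ok_roles <- c("loop", "technical_replicate", "dye_swap", "mock")
  bad <- setdiff(unique(design$role), ok_roles)
  if (length(bad)) stop("unknown slide role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(design$slide_id)) stop("duplicate slide_id in design")
  mocks <- design[design$role == "mock", ]
  if (any(mocks$cy3_sample != mocks$cy5_sample)) {
    stop("mock slides must carry the same sample in both channels")
  }
  nonmock <- design[design$role != "mock", ]
  if (nrow(nonmock) > 0 &&
      !samples_connected(nonmock, unique(c(nonmock$cy3_sample, nonmock$cy5_sample)))) {
    stop("non-mock slide graph is not connected; some contrasts inestimable")
  }
  invisible(design)
}

#' Connectivity of a set of samples through a set of slides
#'
#' Breadth-first search over the graph whose nodes are samples and whose
#' edges are slides (each slide connects its Cy3 and Cy5 sample). Used both
#' for design validation and, per gene, to reason about which contrasts the
#' available slides can estimate.
#'
#' @param slides `data.frame` with `cy3_sample`, `cy5_sample`.
#' @param samples Character vector of sample ids that must be mutually
#'   reachable.
#' @return `TRUE` if all `samples` lie in one connected component.
#' @export
samples_connected <- function(slides, samples) {
  if (length(samples) <= 1) return(TRUE)
  if (nrow(slides) == 0) return(FALSE)
  nodes <- unique(c(slides$cy3_sample, slides$cy5_sample, samples))
  adj <- split(
    c(slides$cy5_sample, slides$cy3_sample),
    factor(c(slides$cy3_sample, slides$cy5_sample), levels = nodes)
  )
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  queue <- samples[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen[samples])
}

#' Read / write a design sheet
#'
#' The design sheet is a CSV with columns `slide_id`, `cy3_sample`,
#' `cy5_sample`, `role`.
#'
#' @param path File path.
#' @return `read_design` returns the validated design `data.frame`.
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_loop_design(d)
  d
}

#' @param design Design table to write.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_loop_design(design)
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
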