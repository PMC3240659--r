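#' Generator configuration
#'
#' Assembles the configuration for the synthetic spot-level data generator.
#' Defaults describe a clean run of a quadruplicate-spotted two-color cDNA
#' platform measuring the 12-sample perturbation series on the 17-slide loop
#' design: five gene archetypes, a log2 effect size of 0.5 for responsive
#' genes, per-gene residual noise, per-gene dye bias, per-(slide, print-tip)
#' intensity-dependent trends that the normalization stage must remove, and a
#' small rate of defective spots that the QC stage must catch.
#'
#' @param n_genes Named integer vector of gene counts per archetype; names
#'   from `steady_up`, `steady_down`, `cumulative_up`, `cumulative_down`,
#'   `flat`.
#' @param effect_size Log2 response amplitude `a` of steady-state genes at
#'   the post-dose time points (T1, T3, T5); cumulative genes ramp to `2a`.
#' @param noise_sd Length-2 range; per-gene residual SD sigma is drawn
#'   uniformly from it (log2 units, per spot).
#' @param dye_bias Length-2 range for the per-gene dye-bias offset gamma
#'   (log2 units).
#' @param replicate_spots Spots printed per gene per slide (quadruplicate by
#'   default).
#' @param defective_spot_rate Probability that a spot is defective; each
#'   defective spot violates exactly one QC criterion (low SNR, small
#'   diameter, or high pixel CV), chosen uniformly.
#' @param print_tip_blocks Number of print-tip groups per slide.
#' @param intensity_baseline Length-2 range of per-spot mean log2 intensity
#'   (the A value about which the two channels are split).
#' @param block_bias_sd SD of the constant log-ratio offset of each
#'   (slide, block) group.
#' @param block_trend_sd SD of the slope of the intensity-dependent log-ratio
#'   trend within each (slide, block) group (per log2-intensity unit about
#'   the baseline midpoint).
#' @param background_floor Mean background intensity (linear scale).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = c(steady_up = 100, steady_down = 100,
                                         cumulative_up = 50,
                                         cumulative_down = 50, flat = 200),
                             effect_size = 0.5,
                             noise_sd = c(0.05, 0.15),
                             dye_bias = c(-0.3, 0.3),
                             replicate_spots = 4,
                             defective_spot_rate = 0.05,
                             print_tip_blocks = 4,
                             intensity_baseline = c(7, 11),
                             block_bias_sd = 0.1,
                             block_trend_sd = 0.05,
                             background_floor = 80,
                             seed = 1) {
  archetypes <- c("steady_up", "steady_down", "cumulative_up",
                  "cumulative_down", "flat")
  if (is.null(names(n_genes)) || !all(names(n_genes) %in% archetypes)) {
    stop("n_genes must be named with archetypes: ",
         paste(archetypes, collapse = ", "))
  }
  if (any(n_genes < 0)) stop("gene counts must be non-negative")
  if (defective_spot_rate < 0 || defective_spot_rate > 1) {
    stop("defective_spot_rate must be in [0, 1]")
  }
  if (replicate_spots < 1 || print_tip_blocks < 1) {
    stop("counts must be positive")
  }
  if (diff(range(noise_sd)) < 0 || min(noise_sd) < 0) {
    stop("noise_sd must be a non-negative range")
  }
  structure(list(
    n_genes = n_genes, effect_size = effect_size, noise_sd = noise_sd,
    dye_bias = dye_bias, replicate_spots = as.integer(replicate_spots),
    defective_spot_rate = defective_spot_rate,
    print_tip_blocks = as.integer(print_tip_blocks),
    intensity_baseline = intensity_baseline,
    block_bias_sd = block_bias_sd, block_trend_sd = block_trend_sd,
    background_floor = background_floor, seed = as.integer(seed)
  ), class = "generator_config")
}

# Deterministic per-gene substream seed so adding genes never perturbs the
# draws of existing ones. 32-bit safe.
substream_seed <- function(seed, index, tag) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729 +
                as.double(tag) * 7919) %% 2147483629)
}

#' Ground-truth gene parameters
#'
#' Draws per-gene truth for the generator: archetype, dye bias gamma,
#' residual SD sigma, a baseline log2 level, and the 12 per-sample relative
#' expression levels lambda. Steady-state genes respond by +/- `effect_size`
#' at the odd (post-dose) time points and relax to 0 at the even ones;
#' cumulative genes ramp monotonically to +/- 2 * `effect_size`; flat genes
#' have all contrasts zero.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` with columns `gene_id`, `archetype`, `gamma`,
#'   `sigma`, and `lambda_<sample>` for the 12 samples.
#' @export
make_truth <- function(config) {
  counts <- config$n_genes
  archetype <- rep(names(counts), counts)
  n <- length(archetype)
  samples <- loop_samples()
  lambda <- matrix(0, n, 12, dimnames = list(NULL, samples))
  gamma <- sigma <- base <- numeric(n)
  a <- config$effect_size
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, 1L))
    gamma[i] <- stats::runif(1, config$dye_bias[1], config$dye_bias[2])
    sigma[i] <- stats::runif(1, config$noise_sd[1], config$noise_sd[2])
    base[i] <- stats::runif(1, -0.5, 0.5)
    contrast <- switch(archetype[i],
      steady_up = a * c(1, 0, 1, 0, 1, 0),
      steady_down = -a * c(1, 0, 1, 0, 1, 0),
      cumulative_up = a * (1:6) / 3,
      cumulative_down = -a * (1:6) / 3,
      flat = rep(0, 6)
    )
    lambda[i, paste0("C", 1:6)] <- base[i]
    lambda[i, paste0("UV", 1:6)] <- base[i] + contrast
  }
  out <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    archetype = archetype, gamma = gamma, sigma = sigma,
    stringsAsFactors = FALSE
  )
  colnames(lambda) <- paste0("lambda_", samples)
  cbind(out, as.data.frame(lambda))
}

#' True per-gene contrasts from a truth table
#'
#' @param truth Output of [make_truth()].
#' @return Numeric matrix (genes x 6) of lambda(UVi) - lambda(Ci), rownames
#'   gene ids.
#' @export
true_contrasts <- function(truth) {
  uv <- as.matrix(truth[, paste0("lambda_UV", 1:6)])
  ctl <- as.matrix(truth[, paste0("lambda_C", 1:6)])
  x <- uv - ctl
  dimnames(x) <- list(truth$gene_id, paste0("x", 1:6))
  x
}

#' Simulate spot-level two-channel measurements over a loop design
#'
#' For each gene x slide x replicate spot, emits foreground/background
#' intensities in both channels such that the background-corrected log2
#' ratio (Cy5 over Cy3) equals gamma_g + lambda_g(Cy5 sample) -
#' lambda_g(Cy3 sample), plus Gaussian noise of SD sigma_g, plus the
#' (slide, block) offset and intensity-dependent trend. A configured fraction
#' of spots are defective; each defective spot violates exactly one QC
#' criterion (low SNR in one channel, small diameter, or high pixel CV in
#' one channel), so QC truth is recoverable. All intensities are strictly
#' positive.
#'
#' @param truth Truth table from [make_truth()].
#' @param design Loop design, e.g. [default_loop_design()].
#' @param config The [generator_config()] used for `truth`.
#' @return A `data.frame` with GPR-like columns (`gene_id`, `slide_id`,
#'   `block`, `row`, `col`, `replicate`, `f635_mean`, `b635_mean`, `b635_sd`,
#'   `cv635`, `f532_mean`, `b532_mean`, `b532_sd`, `cv532`, `diameter_um`;
#'   635 = Cy5, 532 = Cy3) plus generator-truth columns `defective` and
#'   `defect_mode` (dropped by [write_spot_table()]).
#' @export
simulate_slides <- function(truth, design, config) {
  validate_loop_design(design)
  samples <- unique(c(design$cy3_sample, design$cy5_sample))
  missing <- setdiff(paste0("lambda_", samples), names(truth))
  if (length(missing)) {
    stop("truth has no expression level for sample(s): ",
         paste(sub("^lambda_", "", missing), collapse = ", "))
  }
  n_gene <- nrow(truth)
  n_slide <- nrow(design)
  reps <- config$replicate_spots
  per_gene <- n_slide * reps
  nb <- config$print_tip_blocks
  mid <- mean(config$intensity_baseline)

  # (slide, block) print-tip effects: constant offset + trend slope in A
  set.seed(substream_seed(config$seed, 0L, 3L))
  bias <- matrix(stats::rnorm(n_slide * nb, 0, config$block_bias_sd),
                 n_slide, nb)
  slope <- matrix(stats::rnorm(n_slide * nb, 0, config$block_trend_sd),
                  n_slide, nb)

  slide_idx <- rep(seq_len(n_slide), each = reps)
  rep_idx <- rep(seq_len(reps), times = n_slide)
  mu_gene <- function(i) {
    lam <- as.numeric(truth[i, paste0("lambda_", samples)])
    names(lam) <- samples
    truth$gamma[i] + lam[design$cy5_sample] - lam[design$cy3_sample]
  }

  out <- vector("list", n_gene)
  for (i in seq_len(n_gene)) {
    set.seed(substream_seed(config$seed, i, 2L))
    mu <- mu_gene(i)[slide_idx]
    e <- stats::rnorm(per_gene, 0, truth$sigma[i])
    A <- stats::runif(per_gene, config$intensity_baseline[1],
                      config$intensity_baseline[2])
    block <- ((i + rep_idx - 2L) %% nb) + 1L
    m_tot <- mu + e + bias[cbind(slide_idx, block)] +
      slope[cbind(slide_idx, block)] * (A - mid)
    corr5 <- 2^(A + m_tot / 2)
    corr3 <- 2^(A - m_tot / 2)
    bg5 <- config$background_floor * 2^stats::rnorm(per_gene, 0, 0.15)
    bg3 <- config$background_floor * 2^stats::rnorm(per_gene, 0, 0.15)
    bsd5 <- bg5 * 0.08
    bsd3 <- bg3 * 0.08
    cv5 <- stats::runif(per_gene, 0.15, 0.5)
    cv3 <- stats::runif(per_gene, 0.15, 0.5)
    diam <- stats::runif(per_gene, 90, 140)
    defective <- stats::runif(per_gene) < config$defective_spot_rate
    mode <- ifelse(defective,
                   c("snr", "diameter", "cv")[sample.int(3, per_gene,
                                                         replace = TRUE)],
                   "none")
    hit5 <- stats::runif(per_gene) < 0.5  # which channel a defect hits
    f5 <- bg5 + corr5
    f3 <- bg3 + corr3
    snr_fail <- mode == "snr"
    f5[snr_fail & hit5] <- bg5[snr_fail & hit5] + 2 * bsd5[snr_fail & hit5]
    f3[snr_fail & !hit5] <- bg3[snr_fail & !hit5] + 2 * bsd3[snr_fail & !hit5]
    diam[mode == "diameter"] <- 50
    cv5[mode == "cv" & hit5] <- 1.5
    cv3[mode == "cv" & !hit5] <- 1.5
    out[[i]] <- data.frame(
      gene_id = truth$gene_id[i], slide_id = design$slide_id[slide_idx],
      block = block, row = i, col = rep_idx, replicate = rep_idx,
      f635_mean = f5, b635_mean = bg5, b635_sd = bsd5, cv635 = cv5,
      f532_mean = f3, b532_mean = bg3, b532_sd = bsd3, cv532 = cv3,
      diameter_um = diam, defective = defective, defect_mode = mode,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write the GPR-like spot table
#'
#' Tab-separated with header; generator-truth columns (`defective`,
#' `defect_mode`), if present, are dropped on write so the file looks like
#' scanner output.
#'
#' @param spots Spot table from [simulate_slides()] or compatible.
#' @param path File path.
#' @export
write_spot_table <- function(spots, path) {
  keep <- c("gene_id", "slide_id", "block", "row", "col", "replicate",
            "f635_mean", "b635_mean", "b635_sd", "cv635",
            "f532_mean", "b532_mean", "b532_sd", "cv532", "diameter_um")
  utils::write.table(spots[, keep], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param truth Truth table from [make_truth()].
#' @rdname write_spot_table
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
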