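#' Build the per-gene linear system for the loop design
#'
#' Encodes, for each slide carrying the gene, the measurement equation
#' m_k = gamma + lambda(Cy5 sample) - lambda(Cy3 sample) + error over the
#' unknowns gamma (per-gene dye bias) and the 12 per-sample relative levels
#' lambda, with the identifiability constraint lambda(C1) = 0 (only
#' differences of lambda are observable, so the pin is immaterial for the
#' reported contrasts). Mock (self-self) slides are QC-only and excluded.
#'
#' @param gene_ratios `data.frame` with `slide_id` and `m` for one gene
#'   (one row per available slide, replicate spots already averaged).
#' @param design Loop design table.
#' @return A list with the design matrix `X` (columns `gamma`,
#'   `lambda_<sample>` for all samples but C1), response `m`, `slide_id`,
#'   and `params` (column names).
#' @export
build_gene_system <- function(gene_ratios, design) {
  validate_loop_design(design)
  design <- design[design$role != "mock", , drop = FALSE]
  keep <- gene_ratios$slide_id %in% design$slide_id
  gene_ratios <- gene_ratios[keep, , drop = FALSE]
  bad <- setdiff(gene_ratios$slide_id, design$slide_id)
  if (length(bad)) stop("unknown slide id(s): ", paste(bad, collapse = ", "))
  samples <- loop_samples()
  free <- setdiff(samples, "C1")
  params <- c("gamma", paste0("lambda_", free))
  n <- nrow(gene_ratios)
  X <- matrix(0, n, length(params), dimnames = list(NULL, params))
  if (n > 0) {
    X[, "gamma"] <- 1
    d <- design[match(gene_ratios$slide_id, design$slide_id), ]
    for (k in seq_len(n)) {
      if (d$cy5_sample[k] != "C1") {
        X[k, paste0("lambda_", d$cy5_sample[k])] <-
          X[k, paste0("lambda_", d$cy5_sample[k])] + 1
      }
      if (d$cy3_sample[k] != "C1") {
        X[k, paste0("lambda_", d$cy3_sample[k])] <-
          X[k, paste0("lambda_", d$cy3_sample[k])] - 1
      }
    }
  }
  list(X = X, m = gene_ratios$m, slide_id = gene_ratios$slide_id,
       params = params)
}

# Contrast matrix: rows are x_i = lambda(UVi) - lambda(Ci) in the reduced
# (lambda_C1 = 0) parameterization.
contrast_matrix <- function(params) {
  C <- matrix(0, 6, length(params), dimnames = list(paste0("x", 1:6), params))
  for (i in 1:6) {
    C[i, paste0("lambda_UV", i)] <- 1
    ci <- paste0("lambda_C", i)
    if (ci %in% params) C[i, ci] <- -1
  }
  C
}

#' Least-squares expression profile for one gene
#'
#' Solves the gene's system by ordinary least squares (minimum-norm solution
#' via the singular value decomposition when rank-deficient). A linear
#' functional of the parameters is estimable exactly when its coefficient
#' vector lies in the row space of the design matrix; each contrast
#' x_i = lambda(UVi) - lambda(Ci) is tested this way and non-estimable
#' contrasts are reported `NA`, never imputed. The gene is `singular` if any
#' of the six contrasts is non-estimable — equivalently, if some UVi is not
#' connected to its Ci through the gene's available slides.
#'
#' The dye-bias term is shared across a gene's slides; it is separable from
#' the contrasts only when the available slides contain a cycle whose edge
#' orientations do not cancel (true for the full design via the 12-slide
#' loop and the dye swaps). When the term is itself non-estimable it is
#' dropped from the fit (reported as 0 with `gamma_estimable = FALSE`) so
#' that contrast estimability follows slide connectivity alone.
#'
#' @param system Output of [build_gene_system()].
#' @param tol Relative tolerance for rank / estimability decisions.
#' @return A one-row `data.frame`: `x1..x6`, `se1..se6`, `gamma_hat`,
#'   `sigma_hat`, `gamma_estimable`, `singular`, `df_residual`, `n_slides`.
#' @export
estimate_profile <- function(system, tol = 1e-8) {
  X <- system$X
  m <- system$m
  p <- ncol(X)
  empty <- data.frame(t(setNames(rep(NA_real_, 12),
                                 c(paste0("x", 1:6), paste0("se", 1:6)))),
                      gamma_hat = NA_real_, sigma_hat = NA_real_,
                      gamma_estimable = FALSE, singular = TRUE,
                      df_residual = NA_integer_, n_slides = nrow(X))
  if (nrow(X) == 0) return(empty)

  estimable_in <- function(V, cvec) {
    # cvec in rowspace(X) iff projection onto V (rowspace basis) is lossless
    resid <- cvec - V %*% crossprod(V, cvec)
    sqrt(sum(resid^2)) <= tol * max(1, sqrt(sum(cvec^2)))
  }
  sv <- svd(X)
  pos <- sv$d > tol * max(sv$d, 1)
  V <- sv$v[, pos, drop = FALSE]
  gvec <- c(1, rep(0, p - 1))
  gamma_ok <- estimable_in(V, gvec)
  if (!gamma_ok) {
    # dye bias confounded with the contrasts: drop it from the model
    X <- X[, -1, drop = FALSE]
    sv <- svd(X)
    pos <- sv$d > tol * max(sv$d, 1)
    V <- sv$v[, pos, drop = FALSE]
  }
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, m))   # minimum-norm LS
  # unscaled covariance of estimable functionals: V D^-2 V'
  fitted <- X %*% beta
  rss <- sum((m - fitted)^2)
  df <- nrow(X) - rank
  sigma_hat <- if (df > 0) sqrt(rss / df) else NA_real_

  Cm <- contrast_matrix(system$params)
  if (!gamma_ok) Cm <- Cm[, -1, drop = FALSE]
  x <- se <- rep(NA_real_, 6)
  for (i in 1:6) {
    cvec <- Cm[i, ]
    if (estimable_in(V, cvec)) {
      x[i] <- sum(cvec * beta)
      q <- crossprod(sv$v, cvec) * dinv
      se[i] <- if (is.na(sigma_hat)) NA_real_ else
        sigma_hat * sqrt(sum(q^2))
    }
  }
  gamma_hat <- if (gamma_ok) beta[1] else 0
  out <- data.frame(t(setNames(x, paste0("x", 1:6))),
                    t(setNames(se, paste0("se", 1:6))),
                    gamma_hat = gamma_hat, sigma_hat = sigma_hat,
                    gamma_estimable = gamma_ok,
                    singular = anyNA(x),
                    df_residual = as.integer(df), n_slides = nrow(X))
  rownames(out) <- NULL
  out
}

#' Estimate expression profiles for all genes
#'
#' @param ratios Slide-averaged log ratios from [average_replicates()]
#'   (columns `gene_id`, `slide_id`, `m`).
#' @param design Loop design table.
#' @param tol Passed to [estimate_profile()].
#' @return A `data.frame`, one row per gene: `gene_id`, `x1..x6`,
#'   `se1..se6`, `gamma_hat`, `sigma_hat`, `gamma_estimable`, `singular`,
#'   `df_residual`, `n_slides`.
#' @examples
#' cfg <- generator_config(n_genes = c(steady_up = 5, flat = 5),
#'                         noise_sd = c(0, 0), defective_spot_rate = 0,
#'                         block_bias_sd = 0, block_trend_sd = 0)
#' design <- default_loop_design()
#' spots <- simulate_slides(make_truth(cfg), design, cfg)
#' ma <- compute_MA(spots)
#' prof <- estimate_profiles(average_replicates(ma, "M"), design)
#' prof[1, c("x1", "x2", "singular")]
#' @export
estimate_profiles <- function(ratios, design, tol = 1e-8) {
  genes <- sort(unique(ratios$gene_id))
  rows <- lapply(genes, function(g) {
    sys <- build_gene_system(ratios[ratios$gene_id == g, , drop = FALSE],
                             design)
    estimate_profile(sys, tol = tol)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE), out)
}

#' Number of non-singular genes
#'
#' A gene is non-singular when all six contrasts are estimable from its
#' available slides, i.e. each UVi connects to its Ci through the loop.
#'
#' @param profiles Output of [estimate_profiles()].
#' @return Integer count.
#' @export
count_nonsingular <- function(profiles) {
  sum(!profiles$singular)
}

#' Write / read a profile table
#'
#' Tab-separated; missing values encoded as `NA`.
#'
#' @param profiles Output of [estimate_profiles()].
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
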