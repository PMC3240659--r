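# Shared fixtures and independent oracles for the test suite.

# Small clean generator configuration: no noise, no defects, no print-tip
# effects -- the exact measurement-model limit.
clean_config <- function(n_genes = c(steady_up = 5, steady_down = 5,
                                     flat = 5),
                         seed = 11, ...) {
  generator_config(n_genes = n_genes, noise_sd = c(0, 0),
                   defective_spot_rate = 0, block_bias_sd = 0,
                   block_trend_sd = 0, seed = seed, ...)
}

# Spot table -> slide-level log ratios without normalization (clean data).
raw_slide_means <- function(spots) {
  average_replicates(compute_MA(spots), "M")
}

# Independent graph-connectivity oracle: contrast x_i is estimable iff UVi
# and Ci are connected through the available slides (igraph, not the
# package's own BFS or SVD machinery).
connectivity_oracle <- function(available_slides, design) {
  d <- design[design$role != "mock" &
                design$slide_id %in% available_slides, , drop = FALSE]
  nodes <- loop_samples()
  g <- igraph::graph_from_data_frame(
    d[, c("cy3_sample", "cy5_sample")], directed = FALSE,
    vertices = nodes
  )
  comp <- igraph::components(g)$membership
  vapply(1:6, function(i) {
    comp[paste0("UV", i)] == comp[paste0("C", i)]
  }, logical(1))
}

# Slide-availability table for one gene (m = 0 placeholder values).
gene_ratio_stub <- function(slide_ids) {
  data.frame(gene_id = "G0001", slide_id = slide_ids,
             m = rep(0, length(slide_ids)), n_spots = 1,
             stringsAsFactors = FALSE)
}
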