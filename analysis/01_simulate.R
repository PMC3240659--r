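#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study. Twelve samples (C1-C6 controls,
# UV1-UV6 irradiated at time points T1-T6) measured on 17 two-color slides
# in a closed loop with two dye swaps, two technical replicates and one
# mock self-self slide; quadruplicate spots per gene per slide. Ground
# truth (archetypes, dye biases, noise levels) is written alongside so the
# later stages can be scored against it.

library(steadyloop)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- default_loop_design()
cfg <- generator_config(seed = 1)
truth <- make_truth(cfg)
spots <- simulate_slides(truth, design, cfg)

write_design(design, file.path(out, "design.csv"))
write_truth_table(truth, file.path(out, "truth.tsv"))
write_spot_table(spots, file.path(out, "spots.tsv"))

cat("slides:", nrow(design), "(",
    sum(design$role == "loop"), "loop,",
    sum(design$role == "dye_swap"), "dye-swap,",
    sum(design$role == "technical_replicate"), "technical,",
    sum(design$role == "mock"), "mock )\n")
cat("genes:", nrow(truth), "->", nrow(spots), "spots\n")
print(table(truth$archetype))
cat("planted defective spots:", sum(spots$defective),
    sprintf("(%.1f%%)\n", 100 * mean(spots$defective)))
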