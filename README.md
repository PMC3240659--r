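# steadyloop

Detecting transcriptomic steady states from repeated small perturbations,
measured on two-color cDNA microarrays in a loop design.

A system at steady state responds to a small perturbation and relaxes back
before the next one. Given paired control/treated samples harvested 30
minutes after each of three repeated doses (time points T1, T3, T5) and 8
hours after each (T2, T4, T6), a steady-state responder's per-gene contrast
profile `x = (x1..x6)`, with `x_i = lambda(UVi) - lambda(Ci)` in log2
units, alternates between a response level and a relaxed level.
`steadyloop` implements the full inference chain for finding such genes:

1. **Spot QC** — a spot is valid iff SNR `(signal - background) / SD(background)`
   > 5 in both channels, diameter > 75 µm, and pixel CV < 100% in both
   channels (strict inequalities).
2. **Within-print-tip normalization** — robust loess detrending of M on A
   per (slide, print-tip) group.
3. **Loop estimation** — per gene, least squares on
   `m_k = gamma + lambda(Cy5_k) - lambda(Cy3_k) + eps` across the 16
   non-mock slides of a 17-slide loop design (12-slide closed loop, 2 dye
   swaps, 2 technical replicates, 1 mock); contrasts whose samples are
   disconnected by missing spots are flagged non-estimable (*singular*
   genes), never imputed.
4. **Steady-state model fitting** — genes with profile SD > 0.21 are scored
   by the correlation `R` between `x` and the ideal pattern
   `v = (r, s, r, s, r, s)`, which reduces to
   `R = (mean(x[odd]) - mean(x[even])) / (2 SD_pop(x))`; under the null, R
   has density `f(r) = 0.75 (1 - r^2)` on [-1, 1] (verified by simulating
   10^6 null profiles), and `R > 0.75` / `R < -0.75` declare class I
   (up-then-relax) / class II (down-then-relax).

A synthetic spot-level generator with known ground truth (gene archetypes,
dye biases, noise, print-tip trends, planted defective spots) makes every
stage testable end-to-end without external data.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`Rscript analysis/01_simulate.R` … `04_steady_state.R`). In brief:

```r
library(steadyloop)

design <- default_loop_design()            # 17 slides, 12 samples
cfg    <- generator_config(seed = 1)       # 500 genes, 5 archetypes
truth  <- make_truth(cfg)
spots  <- simulate_slides(truth, design, cfg)

filt    <- filter_spots(spots)             # QC
ratios  <- normalize_within_print_tip(compute_MA(filt$valid))
prof    <- estimate_profiles(average_replicates(ratios), design)
calls   <- classify_steady_state(prof)     # SD > 0.21, |R| > 0.75

filt$report$fraction_valid                 # 0.950 (5% planted defects)
count_nonsingular(prof)                    # 500
sum(calls$passed_sd_filter)                # 299
table(calls$label)                         #  up: 99  down: 100  none: 301
```

Of the 200 planted steady-state genes, 199 are recovered in the correct
class (99.5%); none of the 200 flat genes is called (the SD filter removes
them before the `|R|` rule's 8.6% null tail could admit any). The null
calibration itself:

```r
simulate_null(1e6, seed = 271828)
#> density at R = 0: 0.7542 (analytic 0.7500)
#> KS distance to analytic CDF: 0.00068
#> P(|R| > 0.75): 0.08587   (exact: 0.0859375)
```

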