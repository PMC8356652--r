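# slns — self-learning network-based segmentation of brain MR slices

`slns` locates tumor-like regions in 2-D brain magnetic-resonance slices.
It is written for image-analysis practitioners who want a fully inspectable,
deterministic implementation of the HARIS-style two-phase segmentation
heuristic together with the surrounding pipeline — denoising, thresholding,
classification, evaluation — and a synthetic phantom generator with exact
ground truth so that every stage is testable without any external data.

## The method

A slice passes through five stages:

1. **Adaptive bilateral filter.** Each pixel becomes the fuzzy-weighted
   centroid of its neighbourhood,
   `sum(c^x · i) / sum(c^x)` with membership
   `c = exp(−d²/2r²) · P(same class | Δi)`; the center's own value is
   replaced by a contra-harmonic brightness target `Σi²/Σi` estimated from
   same-class neighbours. Constant images are exact fixed points; edges are
   preserved by the Bayesian same-class factor on intensity differences.
2. **Fuzzy-entropy thresholding (FET).** An exhaustive scan of all 254
   interior cuts minimizing the histogram-weighted binary Shannon entropy of
   fuzzy class memberships `μ(i) = 1 / (1 + |i − μ_side|/255)`.
3. **HARIS phase 1 — region count.** Every candidate k in `[k_min, k_max]`
   is scored by `w_x · norm(σ²_between) + w_y · norm(1 − mean I_corl)`,
   where `σ²_between = Σ w_c (μ_c − μ)²` is the between-class variance and
   `I_corl = σ_s²/(σ_s² + σ_i²)` the intraclass correlation; the smallest k
   on the score plateau wins.
4. **HARIS phase 2 — region assembly.** An exact 1-D dynamic-programming
   partition of the intensity histogram refined by Lloyd reassignment;
   each region carries a *local-best feature pixel* (the member nearest the
   region median).
5. **Classification.** The adaptive structural-similarity index
   `ASSI(p,q) = ω · x(p,q)^α · y(p,q)^β · z(p,q)^γ` with the standard SSIM
   luminance/contrast/structure factors and a noise-confidence weight
   `ω = σ_p²/(σ_p² + σ_e²/2)`; regions whose correlation index against a
   tumor reference patch exceeds the threshold are tumorous
   (`CI > Threshold`). A fuzzy-membership variant reassigns pixels by the
   homogeneity-scaled distance `|i − vertex|/(1 − mem)` instead.

Runs append their choices (chosen k, FET threshold, class profile, tumor
reference patch) to an append-only **experience store**; later runs
warm-start from it — the "self-learning" contract. Evaluation reports
sensitivity, specificity, accuracy, the Jaccard similarity index (JSI), the
Matthews correlation coefficient (MCC) and tumor burden (core, enhancement
rim, whole tumor).

## Worked example

```r
library(slns)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 128x128, noise SD 5, 1 tumor
cfg <- run_config(haris = list(k_min = 2, k_max = 8))
rep <- run_pipeline(ph$image, ph$labels, cfg)

rep$k                #> 4
rep$fet_threshold    #> 11
rep$tumor_pixels     #> 322
rep$metrics$dice     #> 0.9984448
rep$region_stats
#>   label pixel_count      mean        sd best_row best_col best_intensity
#> 1     1        5956  10.38486 0.8946152       15        8       10.36928
#> 2     2        8710 110.06421 0.6548350       69       43      110.03754
#> 3     3         322 189.69913 2.0235839       81       43      189.79742
#> 4     4        1396 219.82374 0.9712801       22       25      219.88980
```

Reading the output: the sweep selected k = 4 regions (background, brain,
tumor, skull — their means are recovered in `region_stats`); the FET cut at
intensity 11 separates background from tissue on this phantom; the
classifier marked 322 pixels tumorous against the 321-pixel ground-truth
disk, a Dice overlap of 0.998. With a truth map supplied the report also
carries the full five-metric table, and `tumor_burden(ph$labels)` returns
the core/rim/whole-tumor pixel areas.

The command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "slns.R", package = "slns"))')
Rscript $CLI simulate --out ph --n 2 --seed 4
Rscript $CLI segment  --input ph/phantom_001.png --truth ph/phantom_001_truth.png \
                      --out seg --store exp.jsonl
Rscript $CLI evaluate --pred seg/phantom_001_mask.png --truth ph/phantom_001_truth.png \
                      --report eval.json
Rscript $CLI experience show --store exp.jsonl
```

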