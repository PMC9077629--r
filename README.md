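# insuladiv

Does insularity — the joint condition of small population size and
geographic isolation — actually reduce genetic diversity (GD) within
populations and inflate divergence among them? Published comparisons
disagree, and meta-analyzing them is awkward: studies report incompatible
metrics (heterozygosity, allelic richness, nucleotide diversity,
F<sub>ST</sub>, Nei's distance, ...), rarely with variances.

`insuladiv` implements a paired, study-internal synthesis for this problem,
aimed at population geneticists and conservation biologists doing
quantitative literature reviews. Each study unit contributes one point
(x = non-insular aggregate, y = insular-related aggregate) on a common
z-standardized scale, so that under "no effect" every point lies on the
one-to-one line y = x. The pipeline:

1. **validates** literature records against inclusion criteria (≥ 3
   populations, ≥ 1 insular, ≥ 2 non-insular, usable measurements), with an
   exclusion log;
2. **standardizes** each metric type to mean 0 / sd 1 across the corpus,
   collapses studies to paired points (within-population and
   among-population sides independently), and shifts each side so its
   minimum coordinate is 1;
3. **fits** a candidate suite per side: the one-to-one null (slope 1,
   intercept 0), a semi-null (free slope through the origin), a free linear
   model, log- and exp-transformed curves, and a segmented (broken-stick)
   model fitted by iterative linearization — with sum-to-zero taxon-group
   effects on the within side;
4. **ranks** the suite by AICc = 2k − 2logL + 2k(k+1)/(n−k−1), Akaike
   weights w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2), and evidence ratios w_i/w_j;
5. **adjudicates** among four hypotheses — `null`, `proportional`,
   `above_threshold`, `below_threshold` — from the winning model's geometry
   (slope b, crossing x\* = a/(1−b) with the one-to-one line, observed
   x-range), and classifies each study against a 95% band around the
   one-to-one line.

A seeded synthetic meta-dataset generator with known ground truth (including
a population-genetics preset built on Wright–Fisher drift decay
H_t = H₀(1 − 1/2N_e)^t and island-model F_ST ≈ 1/(1+4Nm)) makes every stage
— and end-to-end verdict recovery — testable without any download. See the
methods vignette (`vignettes/paired-insularity-analysis.Rmd`) for the model
details and design choices.

## Worked example

Generate a literature-sized corpus (54 study units) in which insularity
erodes diversity only above a latent threshold, run the full pipeline, and
read the report:

```r
library(insuladiv)

cfg <- synth_config(n_studies = 54, regime = "above_threshold", seed = 1)
run <- run_pipeline(synth = cfg)
run
#> <gd_run_report>
#>   within: n = 54 studies; verdict: above_threshold (best model log_transformed, weight 0.756)
#>   among: n = 54 studies; verdict: above_threshold (best model broken_stick, weight 0.928)

run$sides$within$table[, c("model", "delta_aicc", "weight")]
#>   model           delta_aicc weight
#> 1 log_transformed —          0.756
#> 2 broken_stick    3.2        0.150
#> 3 linear          4.2        0.093
#> 4 semi_null       37.3       <0.001
#> 5 exp_transformed 46.1       <0.001
#> 6 null            92.1       <0.001

run$sides$within$verdict$narrative
#> Side 'within': classifier 'log_transformed' (of 1 model(s) within 2 AICc
#> of best); fitted curve departs from the one-to-one line above x = 2.518.
#> Verdict: above_threshold.
```

The comparison table is the publication-style summary: models sorted by
ΔAICc (best shown as "—"), Akaike weights to three decimals (`<0.001` below
0.0005). Here the log-transformed curve dominates (weight 0.756), the
one-to-one null is rejected outright (ΔAICc 92.1), and the fitted curve
leaves the one-to-one line above x ≈ 2.5 — the generating regime
(`above_threshold`, threshold at the 40th percentile of the baseline range)
is recovered. `run$sides$within$bands` additionally labels each study
against the 95% band around the one-to-one line;
`plot_paired_points(points, fits)` and `autoplot(comparison)` draw the
paired plot and the weight profile.

Real data enter the same way via `read_records("gd_records.csv",
"divergence_records.csv")` (CSV schemas and column mapping documented in
`?read_records`), then `run_pipeline(records = rs)`.

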