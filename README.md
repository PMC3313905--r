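# gcresist

A complete, tested R pipeline for two-channel cDNA microarray studies of
glucocorticoid (GC) response in leukemic cells, ending in a classification
of the observed resistance as **inherent** (present before treatment) or
**acquired** (developed under treatment).

GCs such as prednisolone are first-line drugs in lymphoid malignancies
because they drive lymphoid cells into apoptosis; resistant cells blunt
this response, and whether the resistance is hard-wired or adaptive has
direct clinical meaning. gcresist takes raw two-channel slide tables from
a dose/time-course design — a triplicated loop design at 4 h (contrasts
'1' control vs low dose, '2' low vs high, '3' control vs high) plus
single slides at 72 h ('4' intermediate vs high, '5' control vs high) on
a second platform — and runs the full chain:

1. **rLsBC background correction** — per channel, a robust loess of log2
   background on log2 foreground is subtracted: `Fc = F − Bl`,
   `fc = 2^Fc` (multiplicative noise model).
2. **Replicate averaging** by geometric mean, then iterative exclusion of
   intensities more than 3 IQR outside the quartiles.
3. **M-A loess normalization** — `M = F^R − F^G`, `A = (F^R + F^G)/2`;
   a robust local-quadratic loess (span 10%) of M on A is subtracted.
4. **Loop-design filter** — the loop discrepancy `LdF = M1 + M2 − M3`
   should be zero; features beyond mean ± 2 SD of LdF are removed
   everywhere downstream.
5. **Integration** — reporters map one-to-one to gene identifiers, the
   platform gene lists intersect into the common gene set (CGS), and
   **median rank score (MRS) normalization** replaces each non-reference
   experiment's rank-r value by the reference experiments' rank-r median.
6. **DE calling** — intensity-dependent Z-scores from a sliding window
   (20% of features, ordered by A): `Z = (M − μ_local)/σ_local`,
   two-sided at 95% (`|Z| ≥ 1.96`), labels U / D / S per experiment.
7. **Clustering** — top-100 genes by SD (SD100), restarted k-means
   (squared Euclidean), number of clusters chosen by the maximum average
   silhouette width `S̄_k`, `S_i = (b_i − a_i)/max(a_i, b_i)`, over
   k = 2..30.
8. **Enrichment** — parent-child-union overrepresentation on a GO-style
   DAG against the CGS: each term's hypergeometric universe is the genes
   annotated to the union of its parents; upper-tail p-values, raw
   p < 0.05.
9. **Verdicts** — per-experiment U/D/S sets, their ten named
   intersections (S1∩S3, U1∩U3, D1∩D3, U1∩D3, D1∩U3 and the 72 h
   counterparts), and a rule engine translating each set's enriched
   functional categories (`F_p` apoptosis evasion / proliferation vs
   `F_a` apoptosis induction / arrest) into
   inherent / acquired / undefined.
10. **Chromosome mapping** — per-chromosome gene counts and sign-split
    mean expression with pairwise Pearson correlations.

A first-class synthetic-data generator (`sim_config()`,
`simulate_study()`, …) emulates the whole design with known ground truth
— loop-consistent planted fold changes, multiplicative background,
injected dye bias, overlapping platforms with mapping defects, planted
clusters and a planted enriched ontology term — so every stage is tested
without any external data.

## Worked example

```r
library(gcresist)

cfg    <- sim_config(n_features = 600, de_fraction = 0.05,
                     de_effect = 1.5, seed = 1)
study  <- simulate_study(cfg)                 # slides + mapping + ontology + maps
params <- pipeline_params(k_max = 10, n_init_select = 100,
                          n_init_final = 100, seed = 1)
res    <- run_pipeline(study, params)
res
#> gcresist pipeline result
#>   common gene set: 95 genes
#>   optimal k: 9 (mean silhouette 0.851)
#>   verdicts: inherent=4, not_applicable=5, undefined=16

subset(tidy(res), resistance == "inherent")
#> # A tibble: 4 × 5
#>   set_label n_genes categories resistance qualified
#>   <chr>       <int> <chr>      <chr>      <lgl>
#> 1 D1∩D3           2 F_a        inherent   FALSE
#> 2 D1              4 F_a        inherent   FALSE
#> 3 D3              3 F_a        inherent   FALSE
#> 4 U3              4 F_p        inherent   FALSE
```

Reading the output: 95 of the simulated genes survive mapping and
filtering into the CGS; the silhouette curve peaks at k = 9 clusters;
and the genes down-regulated at *both* prednisolone doses at 4 h
(`D1∩D3`), being enriched for apoptosis-inducing functions (`F_a`),
indicate an inherent resistance mechanism — the cells are switching off
their own death program rather than learning to — exactly the planted
structure of this simulation. Sets with no relevant enrichment stay
`undefined` ("n/d"); empty intersections are `not_applicable`.

Each stage is equally usable on its own (`background_correct_rlsbc()`,
`normalize_loess_ma()`, `loop_design_filter()`, `mrs_normalize()`,
`call_de()`, `select_optimal_k()`, `parent_child_union_ora()`,
`classify_resistance()`, …), all tibble-in/tibble-out and pipeable, with
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures. A thin
command-line wrapper lives in `inst/cli/gcresist.R`
(`simulate` / `run` subcommands); file-based runs are driven by a YAML
configuration (`write_study_inputs()`, `load_pipeline_inputs()`).

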