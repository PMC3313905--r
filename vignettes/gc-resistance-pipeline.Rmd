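---
title: "Methods: the gcresist two-channel microarray pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gcresist two-channel microarray pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcresist)
```

# The scientific question

Glucocorticoids (GCs) such as prednisolone are first-line drugs against
lymphoid malignancies because they induce apoptosis in lymphoid cells
through the glucocorticoid receptor (GR). Leukemic cells, however, are
often resistant, and it matters clinically *how*: cells may carry the
resistance before any exposure (**inherent / intrinsic** resistance) or
develop it while adapting to the drug (**acquired** resistance).

gcresist implements a complete computational pipeline that addresses this
question from two-channel cDNA microarray experiments of a GC-treated
leukemic cell line, measured at an early (4 h) and a late (72 h) time
point at several drug doses. The five experimental contrasts it expects
are labelled '1' (control vs low dose, 4 h), '2' (low vs high dose, 4 h),
'3' (control vs high dose, 4 h), '4' (intermediate vs high dose, 72 h)
and '5' (control vs high dose, 72 h). Experiments 1–3 form a loop design
(triplicate hybridizations each), experiments 4–5 are single slides on a
second, larger platform.

The pipeline's output is a table of **verdicts**: for each biologically
meaningful gene set, whether its functional enrichments point to an
inherent or an acquired mechanism of resistance, or leave the question
undefined.

# Stage by stage

## Background correction (rLsBC)

Per channel (red `R`, green `G`) the log2 background `B` is regressed on
the log2 foreground `F` with a robust loess, and the fitted value `Bl` is
subtracted: `Fc = F − Bl`, `fc = 2^Fc`. Using the *regression estimate*
of the background rather than each spot's local background reflects the
assumption that background contamination acts multiplicatively on raw
intensities, so it is additive (and smooth in `F`) on the log scale.

Numerical choices: the background regression uses a local-linear loess
(`degree = 1`) with span 0.3 — the smoothing parameter of this fit is a
package default, chosen wide because the background trend is expected to
be slowly varying; it is a configurable parameter of every entry point.
Both loess fits use `surface = "direct"`, so data lying exactly on a
polynomial of the local degree is reproduced to machine precision, which
makes the noiseless limits of the generator exactly recoverable.
Robustness uses bisquare reweighting (4 iterations); when a plain fit is
already exact (residual magnitude below `1e-8` relative), the robust
refit is skipped, because bisquare weights are undefined at zero residual
MAD.

## Replicate averaging and outlier exclusion

Replicate corrected intensities are combined by their geometric mean per
channel, `fa = (∏ fc_r)^(1/n)` — the natural average under the
multiplicative model, and exactly scale-equivariant. A feature missing in
some replicates is averaged over the remaining ones when at least two
remain, otherwise masked; single-slide experiments pass through.

Extreme intensities are then masked per channel: values deviating more
than 3 interquartile ranges from the first or third quartile (type-7
quartiles, `IQR = Q3 − Q1`) are excluded, and the quartiles are
recomputed on the survivors until a fixed point. The exclusion operates
on the log2 averaged intensities; a constant vector is never trimmed
(IQR 0 keeps everything), and the iteration refuses to shrink below 4
values. Whether exclusion runs before or after averaging is genuinely
open; it runs after averaging here, where a replicate-consistent spike is
still visible but single-replicate noise has been damped.

## M-A normalization

With `M = F^R − F^G` and `A = (F^R + F^G)/2`, intensity-dependent dye
bias appears as a trend of `M` against `A`. A robust loess with a local
*quadratic* model and span 0.10 is fitted to the M-A scatter and
subtracted: `M_norm = M − loess(A)`; `A` is unchanged. The 10% span
suits the small probe counts of these arrays; the fit requires at least
20 usable features and errors out when the span leaves local windows
with fewer than 3 points.

A loess smoother is not a projection: under noise, re-normalizing an
already-normalized profile can still move points slightly (with noise SD
0.1 the second pass moves points an order of magnitude less than the
first). In the noiseless limit normalization is exactly idempotent, and
an exactly quadratic trend is removed to below `1e-6`.

## Loop-design filter

For the loop of experiments 1–3, ratios must compose:
`(f1R/f1G)·(f2R/f2G) = f3R/f3G`, i.e. `LdF = M1 + M2 − M3 = 0`
feature-wise. Features whose `LdF` deviates more than 2 SD from the mean
`LdF` are eliminated, and the removal propagates to all downstream
analyses (including the 72 h experiments, through the common gene set).
Note the band is relative to the empirical spread: on data that is loop
consistent up to floating-point jitter, the filter still trims the ~4.5%
tail of that jitter — the magnitude of `LdF` itself, not the retained
fraction, is the correctness criterion.

## Cross-platform integration

Reporters are mapped to gene identifiers through a user-supplied
two-column table (the original lookup service is out of scope). The
one-to-one requirement is enforced *within each platform's profile*:
unmapped reporters, duplicated mapping rows, and groups of reporters
sharing a gene are dropped, with counts logged. The **common gene set
(CGS)** is the sorted intersection of the per-platform gene lists; an
empty CGS is an error.

**Median rank score (MRS) normalization** then removes platform/batch
differences: per-rank medians are computed over the reference
experiments (the larger platform's experiments '4' and '5', pooled), and
each non-reference experiment's value at rank r is replaced by the
reference median at rank r. The normalized values are a permutation of
the reference medians — distributions become identical as multisets —
while the target's rank order is exactly preserved. Ties are broken
deterministically by `(value, gene_id)`. The values normalized are the
log ratios `M` restricted to the CGS (the integrated output is a
fold-change matrix); reference experiments pass through untouched.
Integration runs before DE calling, so all statistics operate on the
unified matrix.

## Differential expression: intensity-dependent Z-scores

Features are sorted by `A`; each feature's local mean and SD of `M` are
computed over a sliding window of 20% of the features, centred on the
feature's rank and shifted inward at the extremes so the window never
shrinks (a full-width window therefore reproduces the global mean/SD).
Then `Z = (M − mu_local)/sd_local`, thresholded two-sided at the 95%
confidence level (`z_crit ≈ 1.96`, inclusive): `U` for `Z ≥ z_crit`, `D`
for `Z ≤ −z_crit`, `S` otherwise. Two-sided is the right reading because
both the up- and down-regulated sets feed the decision logic. No
multiple-testing correction is applied by default (an optional
Bonferroni/BH flag exists on the enrichment side); under a pure null
about 95% of features are labelled `S` by construction, which is the
calibration the acceptance script verifies. The original description
references smoothed window statistics; plain per-window statistics are
used here, a documented approximation.

## Clustering and the number of clusters

Genes are ranked by the sample SD of their profile across the five
experiments and the top 100 kept (SD100). k-means with squared Euclidean
distance is restarted from random data-point seedings — 1,000 restarts
per k while scanning k = 2..30, recording for each k the best (maximum)
average silhouette width `S̄_k` over the restarts; the optimal k is the
argmax (ties to the smallest k). The final clustering at k* is the
best-of-100-restarts run minimizing the within-cluster SSE.
Silhouettes use the squared Euclidean distance too:
`S_i = (b_i − a_i)/max(a_i, b_i)`, singleton clusters scored 0, as are
points with `a_i = b_i = 0`.

Implementation notes: restarts call `stats::kmeans` (Hartigan–Wong) from
explicitly sampled distinct data points; a degenerate seeding (duplicate
points or an empty-cluster failure) is retried with a fresh draw, which
preserves the best-of-restarts semantics. The master seed is split
deterministically into per-k and per-restart seeds, so results are
exactly reproducible.

## Enrichment: parent-child-union overrepresentation

Study sets are tested for term overrepresentation against the CGS as the
reference, on a single-root is-a DAG with true-path–propagated
annotations (a gene annotated to a term is annotated to all its
ancestors). The **parent-child-union** statistic conditions each term's
hypergeometric universe on the genes annotated to the union of its
parents: drawing `n_study_parents` genes from the `n_pop_parents`-gene
universe containing `n_pop_term` term genes, the p-value is the upper
tail `P(X ≥ n_study_term)`. Conditioning on the parents prevents the
cascade of false positives below a genuinely enriched ancestor that the
term-independent test suffers from. The root is skipped, as are terms
with an empty parent universe or no reference annotation (skipped, not
scored 1, to avoid inflating result lists). Raw p < 0.05 is the default
significance rule, matching the study's reporting.

Significant terms are mapped to functional super-categories through a
user-supplied table: `F_p` (apoptosis evasion, cell-cycle progression —
the undesired direction under GC therapy) and `F_a` (apoptosis
induction, cell-cycle arrest — the desired one); additional categories
(e.g. metabolic `F_m`, inflammatory/NF-κB `F_i`) are carried through but
do not drive verdicts.

## The verdict rule engine

Per experiment the genes partition into `U_i`/`D_i`/`S_i`, and ten named
intersections are formed (`S1∩S3`, `U1∩U3`, `D1∩D3`, `U1∩D3`, `D1∩U3`;
`S4∩S5`, `U4∩U5`, `D4∩D5`, `U4∩D5`, `D4∩U5`). Each set's enriched
categories are translated into a verdict by a rule table; for example,
genes down-regulated at both doses at 4 h (`D1∩D3`) with apoptosis-
inducing functions (`F_a`) indicate an *inherent* mechanism — the cell
is switching off its own death program — while the same set enriched for
`F_p` indicates gradually developing (*acquired*) resistance. The late
(72 h) rules are asymmetric: several branches can only support
"acquired" or leave the verdict undefined, reflecting that homeostatic
feedback dominates late responses. Rules for the individual `U_i`/`D_i`
sets mirror the published per-set verdicts; they are not fully
formalized in the original methods, so the table is exposed and
user-overridable (`resistance_rules()`), keeping the judgment call
visible. A set with no relevant enrichment is `undefined` ("n/d"); an
empty set is `not_applicable`; when both `F_p` and `F_a` fire, both
sub-verdicts are reported and the overall call is mixed/undefined. The
published "~ inherent" qualification is carried as a `qualified` flag.

Clusters are additionally summarized behaviourally: a cluster's mean
`M` per experiment is thresholded at `z_crit ×` the experiment's median
local SD, giving labels like `~D5` (down only in experiment '5'); when
the behaviour matches a single rule-table set the cluster inherits that
rule.

## Chromosome-level aggregation

Pooling `M` over genes × experiments per chromosome (scopes: all, 4 h,
72 h), the positive and negative values are averaged separately (zero
values enter neither mean — the headers are strict inequalities), and
all pairwise Pearson correlations between gene counts and the sign-split
means are computed with two-sided p-values, pairwise-complete over
chromosomes with defined values.

# The synthetic-data generator

The generator emulates the study's structure so that every stage is
testable with known ground truth and no download: triplicate loop slides
for experiments 1–3 whose planted log ratios satisfy `M1 + M2 = M3`
exactly; single slides for 4–5; two platforms with overlapping gene
content and a reporter mapping containing deliberate violations
(unmapped reporters, a many-to-one group); cluster-structured profile
matrices; and random single-root ontologies with a planted enriched
term.

Generative model (defaults in `sim_config()`): true green-channel log2
abundances uniform on 6..16 (a raw dynamic range of 2^6..2^16 — not
stated by the original study, configurable); observed log2 foreground =
signal + ε with `ε ~ N(Bl(signal), background_noise_sd)` and the
recorded background channel `Bl(signal)` plus noise of the same SD,
where `Bl(F) = 4 + 0.25·F` — a linear trend inside the loess model
class, so the noiseless limit is corrected exactly. Dye bias is a
quadratic polynomial in `A` added to the red channel, removable exactly
by the quadratic M-A loess in the noiseless limit. Differential
expression is planted in 5% of features at ±1.5 log2 units (the study's
DE sets are a few percent of its 490-gene integrated matrix, with
fold changes of that order); background noise defaults to 0.1 log2
units. `simulate_study()` additionally annotates the planted up/down
genes of the early experiments under dedicated terms mapped to
`F_p`/`F_a`, so the verdict logic has signal to find. Truth tables are
returned (and written) separately from the slide files and are never
referenced by the pipeline configuration.

What the generator does **not** emulate: spot morphology and spatial
artefacts (print-tip gradients, scratches), correlated noise between
channels, platform-specific probe effects beyond gene content, and
annotation bias of real GO. Passing tests on this generator therefore
demonstrates the correctness of the computations, not robustness to
every artefact of real slides — in particular the absence of spatial
normalization is a deliberate non-goal.

# Problem sizes and reproducibility

The test-suite and example runs use scaled problem sizes chosen to keep
the statistical claims meaningful at interactive run times: 300–1,000
features per slide, platform pairs of 60–320 genes, k-recovery on
100×5 matrices with 200 restarts per k over k = 2..12 (the full-size
defaults — 1,000 restarts over 2..30 — remain the package defaults),
null calibration at 5,000 features. Every stochastic step takes an
explicit integer seed; a master seed is split deterministically per
stage and per restart, and re-running a pipeline on the same inputs
reproduces byte-identical outputs (the manifest records parameters and
per-file MD5 checksums).

# Known limitations

* Within-slide spatial/print-tip normalization and between-slide
  quantile normalization are out of scope (MRS fills the latter role at
  integration time).
* The sliding-window statistics are unsmoothed; the cited window
  approach allows an extra smoothing pass over overlapping windows.
* The individual-set verdict rules are reverse-engineered from the
  published per-set verdicts and should be reviewed (and, if needed,
  overridden) for any new biological system.
* Real GO releases are large; the bundled reader handles the minimal
  `id`/`name`/`is_a` OBO subset and is not a general OBO parser.
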