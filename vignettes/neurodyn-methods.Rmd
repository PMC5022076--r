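---
title: "Models and methods behind neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neurodyn` analyses replicated transcriptomic time courses of neuronal
differentiation: seven time points (days in vitro 0, 1, 3, 5, 7, 9, 11),
three biological replicates, probe-level summary intensities with
detection p-values as exported from BeadChip scanner software. This
vignette explains each model, the tunable parameters and their defaults,
the numerical choices, and what the accompanying synthetic-data
generator does and does not emulate. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Preprocessing

Raw intensities are log2-transformed and quantile-normalised
(`log2_quantile_normalize()`): each column is mapped onto the
across-sample mean of sorted log2 values, preserving within-column
ranks; ties within a column receive the mean of the reference values
spanned by their rank range. The transform is idempotent and makes all
column distributions identical by construction. Non-positive raw values
are a hard error naming the offending cell, since they indicate a
corrupted export rather than a recoverable condition.

Quantile normalization presumes that most genes are unregulated, so
that column distributions differ only through technical variation. When
regulation is massive and asymmetric this assumption fails and the
transform displaces genuinely flat genes; on noise-free synthetic data
such displacement creates zero-residual artifacts (any displacement
becomes "significant"). `run_pipeline(normalize = "log2")` therefore
skips the distribution-matching step; the validation runs on noise-free
data use it because there is no technical variation to remove. Real
data should use the default `"quantile"`.

Multi-probe genes collapse to the probe with the largest signal
variance across all samples (`collapse_probes()`); variance ties break
by the lexicographically smallest probe ID so the collapse is
deterministic. The analysis universe is the *expressed set*
(`expressed_set()`): genes whose detection p-value is below 0.05 in
**every** sample. This is the strictest reading of "expressed above
background in all replicates"; it fixes one universe for the
differential-expression, warping, component and network stages, while
the full platform universe is kept for enrichment denominators. Sample
QC (`qc_samples()`) clusters samples on 1 − Pearson correlation over
the top 2000 variance genes with average linkage; a sample is a
candidate outlier when its first merge height exceeds the median plus
three interquartile ranges of all merge heights. That cutoff rule is
this package's own: published analyses typically inspect the dendrogram
visually, and an automated rule is needed for reproducibility.

## Differential expression

For each time point *t* versus baseline the model per gene is

$$y_{tr} = \beta_0 + \beta\,\mathbf{1}(\text{div}=t) + b_r +
\varepsilon_{tr},\qquad b_r \sim N(0,\sigma^2_{rep}),\;
\varepsilon \sim N(0,\sigma^2_e),$$

a random intercept per biological replicate. With two dichotomised time
points and balanced replication this is a randomized complete block
design, and the REML variance components equal the classical ANOVA
estimators, so `fit_contrast()` evaluates them in closed form,
vectorised over all genes (the test suite cross-checks the fit against
`lme4::lmer` on balanced data). The fixed effect is the difference of
group means with $\mathrm{Var}(\hat\beta) = 2\sigma^2_e/n_{rep}$.

The reference distribution is the exact small-sample t: with a positive
replicate variance component the Wald statistic is exactly
$t_{n_{rep}-1}$ (the paired-contrast result); when the variance
component is estimated as zero the fit degenerates to ordinary least
squares and the reference is $t_{2n_{rep}-2}$. A normal reference would
treat a $t_2$ statistic as Gaussian — with six observations this is
badly anti-conservative and would break the FDR control the rest of the
pipeline depends on, so the package makes the exact-t choice
deliberately.

Per contrast, `bh_fdr(p, m)` applies Benjamini–Hochberg step-up with an
explicit denominator `m` fixed to the expressed-universe size, so
skipped genes cannot silently weaken the correction. Calls are
`up`/`down` at q < 0.05 by effect sign; a gene may legitimately be up
at one time point and down at another, and then appears in both union
sets and once in `dex_any`.

## Dynamic time warping

Gene trajectories are replicate-mean log2 fold changes versus baseline
(`log2fc_trajectories()`). `dtw_distance()` is classical
dynamic-programming DTW: local cost $|a_i-b_j|$, symmetric
match/insert/delete steps each adding the local cost once, endpoints
aligned, unnormalized accumulated cost. The reference series is the
flat zero trajectory — the statistic measures departure from "no
regulation". Distances against a common reference are evaluated with a
vectorised dynamic program across all genes.

The null calibration (`calibrate_noise_null()`) builds, per noise SD in
a grid (default 0.05–0.30 in steps of 0.05, 200 trajectories per
level), flat trajectories perturbed by Gaussian noise, scores each
against the zero reference, and fits OLS of distance on noise SD. The
dynamic threshold is

$$\tau = 2\,u_0,\qquad u_0 = \hat b_0 + 1.96\,\mathrm{SE}(\hat b_0),$$

twice the upper 95% boundary of the fitted intercept. Two properties of
this rule deserve explicit statement, because they constrain when it is
meaningful:

* The expected DTW distance of pure-noise trajectories is exactly
  proportional to the noise SD, so the true intercept is 0 and τ is a
  small *absolute noise floor*, not a matched-noise null. Genes whose
  trajectory noise is comparable to the calibration grid essentially
  all exceed τ.
* $\hat b_0$ is itself a draw around 0 with spread $\mathrm{SE}$, so τ
  varies several-fold between calibration runs.

Consequently the rule behaves as a null filter only when the data's
replicate-averaged trajectory noise sits well below the calibration
grid. The generator's default residual SD (0.002 log2 units) is chosen
to represent that near-noise-free regime; at realistic array noise the
threshold flags nearly everything, which users should treat as a known
limitation of the published rule rather than of its implementation. A
per-gene matched reading remains available by predicting from the
returned `lm` at a gene's own estimated noise SD.

Dynamic genes are clustered by k-means on the raw trajectories
(Euclidean distance, no scaling), best of `n_init = 50` starts for each
k up to `k_max = 12`. The elbow is the k maximizing the second
difference of the *log* within-cluster sum of squares. On the raw
scale, curvature provably peaks at the first dominant split (k = 2,
typically up- versus down-regulated) whenever cluster separation is
hierarchical; the log scale locates the point of strongest relative
flattening, which is what visual scree inspection identifies. Exact
zeros in the scree curve are floored at $10^{-12}\times$ the total sum
of squares. Clusters are relabelled by descending mean final fold
change, so cluster 1 is always the strongest positive responder.

## Reproducibility-selected ICA

The expressed genes × samples matrix is column-centered and PCA-whitened
to the candidate component count; FastICA with the logcosh contrast and
symmetric decorrelation then runs from `n_iter` (default 250) random
rotations (`run_ica_ensemble()`; convergence tolerance $10^{-4}$, at
most 200 iterations — the conventional defaults; a deflation variant is
available via `method = "deflation"`). Components are matched to a
reference run by optimal one-to-one assignment on absolute load
correlations (`clue::solve_LSAP`) and sign-aligned; the consensus load
per component is the first principal component of the aligned run-load
stack, z-scored, and the reproducibility $\bar r$ is the mean
correlation of run loads with the consensus over **all** runs. Stalled
runs are flagged and counted but not dropped: a component whose
estimation does not settle is genuinely irreproducible, and removing
those runs would bias $\bar r$ upward (the reference tooling for this
style of analysis exposes no convergence status, so its reported means
necessarily included every restart).

`select_component_count()` retains the largest count whose minimum
$\bar r$ exceeds `r_cut = 0.999`. Two structural facts about
restart-based reproducibility on a fixed data set, established during
development and visible in the test suite:

* Counts above the true data rank cannot be whitened and can never
  pass, which is the reliable selection mechanism: on noiseless rank-k
  sources the selector recovers k in the large majority of seeds.
* For two components the optimization is a single rotation angle with
  one sharp empirical optimum even on pure Gaussian noise, so the count
  2 reproduces essentially always; reproducibility alone cannot reject
  it. With substantial isotropic noise, counts beyond the true source
  count can also converge to stable empirical optima. The selector is
  therefore trustworthy in the near-rank-deficient regime and should be
  read as exploratory outside it.

Component membership is $|z| > 3$ on the z-scored consensus loads,
two-sided because load signs are not identifiable.

## Signed co-expression network

`signed_adjacency()` computes $a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta$
with Pearson correlation over all samples; β defaults to 12, the
customary signed-network power, and `pick_soft_threshold()` offers the
scale-free criterion (smallest β with fit R² ≥ 0.8 and negative slope,
falling back with a warning to the best-fitting power). Zero-variance
genes are a hard error listing offenders; the pipeline drops them with
a logged count before building the network.

The topological overlap is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}},\qquad k_i = \sum_{u\neq i} a_{iu},$$

with unit diagonal. Modules are branches of average-linkage clustering
on 1 − TOM under a *static* cut (default height 0.99, minimum size 30);
the published analysis names no dynamic-cut parameters, and a static
cut with two documented knobs is reproducible. Branches below the
minimum size become "grey" (unassigned); modules are named by the
conventional size-ordered color palette, largest first. Module
eigengenes are first principal components of the standardized module
submatrix, sign-oriented to correlate positively with the module mean
profile, computed both on expression (per sample) and on log2
fold-changes (per time point); a single-gene module returns that gene's
standardized profile.

Hub metrics (`hub_metrics()`): Connectivity is the adjacency row sum
(minus the diagonal), per the verbatim "sum of its weighted
correlation" definition — on the adjacency, not the TOM. Degree and
Betweenness are computed on the unweighted graph with an edge where
Spearman ρ strictly exceeds 0.90 (ties at the threshold excluded);
betweenness is standard unnormalized shortest-path betweenness with
equal-length paths splitting the count. Each metric's hub set takes the
top ⌈0.10 · n⌉ genes by descending value, ties broken by gene ID.

## Enrichment

`fisher_enrichment()` forms the 2×2 table of a gene list against a
cluster within a stated universe and sums hypergeometric point masses:
two-sided by default (the analyses this package supports report both
over- and under-representation), with a one-sided mode for DAG
enrichment. The odds ratio is the sample odds ratio $ad/bc$ with a
Haldane 0.5 correction if and only if a cell is zero; log odds ratios
use base e (the published figures never state the base, so the package
documents its choice rather than asserting equivalence).
`enrichment_grid()` corrects over exactly (lists × clusters) tests with
BH and reports at FDR < 0.1 with significance tiers at 0.05 and 0.01.

`rrho_map()` ranks two signed score vectors over a common universe from
most positive to most negative, and for every pair of rank thresholds
(multiples of the bin width, default 200 genes) tests the overlap of
the two top sets with a one-sided hypergeometric test, returning the
−log10 p matrix and its maximum. This is the threshold-set ("stratified
step") formulation.

`go_elim_enrichment()` processes an acyclic term DAG leaves-first; each
term is Fisher-tested one-sided, and a term significant at `p_cut`
(default 0.01) removes its annotated study genes from all ancestors
before they are tested. This is the *elim* decorrelation; the published
weight01 scheme additionally down-weights rather than removes, and that
weighting is deliberately out of scope — elim is the documented
simplification, and with `p_cut = 0` the routine reduces to classical
per-term Fisher tests.

## The synthetic-data generator

`simulate_timecourse()` emulates: a 7 × 3 design on the DIV grid;
linear-scale probe intensities (`2^log2signal`) so preprocessing
genuinely exercises the log2 step; multi-probe genes (a second,
attenuated probe for a configurable fraction, so the variance-collapse
rule always has a deterministic right answer); background genes whose
detection p-values are drawn above 0.05 (expressed genes draw below
0.04, so the detection filter recovers the expressed classes exactly);
planted monotone up/down ramps and a discretized Gaussian transient
bump scaled to a configurable log2 amplitude (default 2); per-gene
replicate offsets (SD 0.1) that constitute the mixed model's variance
component; and latent co-expression factors assigned to flat expressed
genes with positive loadings.

Two construction details keep the zero-noise contracts exact: latent
module curves are built orthogonal (after centering) to the monotone
and transient archetypes, so planted dynamic-class genes carry pure
archetypes and module trajectories cannot masquerade as them; and
module membership is restricted to flat-class genes, so the
last-time-point fold change of a monotone gene equals the configured
effect size exactly when noise is zero. "Dynamic" ground truth for
recovery metrics is the union of the dynamic classes and the module
genes (`truth_dynamic_genes()`), since latent curves are non-flat by
construction.

`simulate_risk_list()` plants a gene list whose expected 2×2 odds ratio
against a truth class equals the request, by solving the quadratic
implied by $\mathrm{OR} = ad/bc$ for the in-class overlap and rounding
to the nearest achievable integer; requests whose rounded overlap would
empty a table cell fail with the maximum achievable value named.

What the generator does **not** emulate: bead-level data, batch or
spatial effects, probe cross-hybridisation, intensity-dependent
variance, or correlated noise between replicates. Passing tests on this
generator therefore demonstrate the correctness of the statistical
machinery and exact recovery in clean regimes, not robustness to the
full messiness of real arrays.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run at desk scale by choice:
synthetic chips of 300–1000 genes, ICA ensembles of 8–25 restarts over
counts 2–6, noise calibrations of 60–200 trajectories per level, and
20-seed batteries for the stochastic properties. All randomness flows
through explicit integer seeds (`local_seed()` restores the caller's
RNG state), and identical configuration plus seed reproduces every
stage bit-identically, which the suite asserts.

## Known limitations

* The DTW noise-floor threshold is structurally fragile (see above);
  with realistic trajectory noise it is not a usable null filter.
* Restart-only ICA reproducibility saturates at two components and
  weakens outside the near-rank-deficient regime.
* Quantile normalization and massive asymmetric regulation interact
  badly on near-noise-free data; `normalize = "log2"` exists for that
  regime.
* The mixed model assumes balanced replication; unbalanced designs are
  rejected rather than approximated.
* GO-style enrichment implements elim decorrelation, not the weight01
  weighting of the reference implementation.
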