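---
title: "Shift-ability screening: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-ability screening: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synshift)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter and why their
defaults are what they are, the numerical conventions that make results
bit-reproducible, and what the synthetic study conditions do — and do not
— establish about real data.

## 1. Treatment-induced expression as the response signal

The package's premise is that how a tumor's transcriptome *moves* under
anti-PD-1 therapy is more informative about outcome than where it starts.
For a paired cohort the induced change of gene $g$ in patient $i$ is

$$\Delta_{gi} = \log_2\frac{x^{\text{on}}_{gi} + c}{x^{\text{pre}}_{gi} + c},$$

computed on the linear scale with pseudocount $c$ (default 1 linear
unit); inputs declared as log2 are exponentiated first. The pseudocount
guards against zeros and its default is negligible relative to typical
linear expression magnitudes. Cohorts without pre/on pairs use *surrogate
changes*: each gene centered on its cohort population baseline (the
per-gene mean by default; the median is available for heavy-tailed
cohorts). Surrogate rows are exactly mean-zero, which the tests assert.

**Signature split.** Per gene, a two-sided Wilcoxon rank-sum test
compares $\Delta_{g\cdot}$ between responders and non-responders; genes
with $p < \alpha$ (default 0.05, raw) join the S signature when the
responder median change is larger, the R signature otherwise. Two
decisions deserve note:

* *Two-sided test with post-hoc direction.* The construction is stated
  directionally per signature (S: higher in responders; R: higher in
  non-responders). Two one-sided tests at the same $\alpha$ would admit
  borderline genes a two-sided test rejects; we use the two-sided test
  with direction assigned by the median difference because it treats both
  signatures symmetrically (label swap provably swaps S and R) and never
  assigns a direction the data cannot support. Significant genes with
  exactly tied medians have no defensible direction and are excluded
  (and reported).
* *No multiplicity correction by default.* Raw $p < 0.05$ matches the
  stated derivation procedure; a Benjamini–Hochberg option exists
  (`adjust = "BH"`) for users who prefer FDR control at the cost of
  smaller signatures.

The test is exact (Mann–Whitney null distribution) when both classes have
at most 10 patients and the gene is tie-free, otherwise the normal
approximation with tie and continuity correction — the same conventions
as `stats::wilcox.test(correct = TRUE)`, against which the vectorized
implementation is verified row by row. Constant genes get $p = 1$ and can
never be selected.

**Classification.** `pca_response_score()` projects samples on the first
principal axis of the gene-centered matrix (no unit-variance scaling:
induced changes are already on a common log2 scale, and scaling would
up-weight near-constant genes). Because a PC sign is arbitrary, the
orientation is fixed deterministically — against the combined signature
score when one is supplied, otherwise by making the largest-magnitude
loading positive. `roc_auc()` is the Mann–Whitney pair-counting AUC with
ties worth one half, checked exactly against an exhaustive pair oracle.

## 2. The enrichment engine

All enrichment computations share one from-scratch weighted-KS core. For
a profile of $N$ genes ranked non-increasingly and a set with $N_h$
members present, the running sum gains $|s_i|^w / \sum_{hits}|s_j|^w$ at
hits and loses $1/(N - N_h)$ at misses; the enrichment score is the
signed maximum deviation from zero (a single two-sided extremum, the
convention under which single signed ES values are reported; pos/neg
split variants are not used). The weight is $w = 1$ throughout the
screen. Numerical conventions:

* **Ranking ties** are broken stably: score descending, then gene id
  ascending, with a locale-independent radix sort. Identical inputs give
  identical rankings on any platform.
* **Extremum ties** (a positive and a negative deviation of equal
  magnitude, which arise with rational step sizes, e.g. at weight 0) are
  broken toward the earliest profile position, with a `1e-9` slack so the
  choice is stable under floating-point summation order. The brute-force
  oracle in the tests implements the same rule independently.
* **Degenerate cases**: all-hit sets have no miss step (ES reaches +1);
  all-zero hit weights fall back to equal increments; empty overlap is an
  error naming the unscorable set; set members absent from the profile
  are dropped and reported via `n_overlap` (standard preranked-GSEA
  practice).

**Permutation null.** A single preranked list admits no phenotype
permutation, so `prerank_gsea()` draws random same-size gene sets without
replacement from the profile — the only feasible null for preranked
input. Sets of equal size share one null sample (the standard
preranked-GSEA economy), NES divides ES by the mean |null ES| of the
matching sign, the nominal p is the add-one-smoothed same-sign tail
count, and FDR is the sign-stratified ratio of tails on pooled null NES.
When no null of the observed sign exists, NES/p/FDR stay `NA` — never
fabricated. Identical seeds reproduce identical results; the caller's RNG
state is always restored.

**ssGSEA.** `ssgsea_score()` ranks one sample's expression descending and
weights hits by rank value $(N - \text{pos} + 1)^\tau$ normalized, with
miss step $1/(N-|S|)$; the score is the sum of the running hit−miss
difference over all positions. The exponent default $\tau = 0.25$ is the
customary single-sample GSEA value (the derivation source does not state
one); it is configurable, and no cross-sample normalization is applied by
default so scores are a pure per-sample statistic.

## 3. The shift-ability screen

For each experiment, $\Delta ES = ES_S - ES_R \in [-2, 2]$. Calls use the
inclusive threshold $\Delta ES \ge 0.7$; "suppresses the R signature" is
operationalized as $ES_R < 0$ and "induces the S signature" as
$ES_S > 0$ (an optional permutation gate exists in `prerank_gsea()` but
the screen is sign- and threshold-based, matching how shifting is
reported). Profiles are retained when their transcriptional activity
score satisfies TAS ≥ 0.4 (inclusive; TAS is consumed as metadata, never
recomputed, since its formula belongs to the upstream resource) and the
gene space is restricted to the declared universe (in the original
resource, 978 landmark + 9,196 best-inferred genes).

**Knockdown efficiency** is deliberately panel-relative: an shRNA
experiment counts as an efficient knockdown when its target-gene z-score
is negative *and* at or below the 25th percentile (linear-interpolation
order statistic, `quantile` type 7, configurable) of that gene's values
across the same-cell-line panel. The negativity bar is absolute — a
target that went up was not knocked down regardless of the panel — while
the percentile encodes "down compared to other experiments in the same
panel". Both knobs are surfaced because only the relative comparison is
specified by the derivation source.

**Concordance and prioritization.** A target is concordant when some
efficient, R-to-S-calling shRNA against it and some R-to-S-calling
compound mapped to it share a cell line — the same-cell-line requirement
is what separates an actionable target from a coincidental shifter. For
prioritization, target expression stands in for target activity:
inhibition aligning with immune activation means a significantly
*negative* Pearson correlation (p < 0.05) between the target's expression
and the class-averaged ssGSEA immune scores. A cancer type counts when
any immune class is significantly negative, and `min_types` (default 1)
types are required. The exact rule that reduced concordant targets to a
prioritized list in the motivating analysis is not fully specified
(how many types, which classes); this parameterization is therefore a
documented choice, not a claim of exact reproduction, and the tests pin
its behavior on planted ground truth at `min_types = 2`.

## 4. Mechanism clustering

Per experiment, expression indicators threshold the level-5-style
z-scores strictly at ±1 (the natural unit of a moderated z-profile; a
value of exactly 1 is *not* called changed). Per-compound consensus
vectors are the integer sums of indicators over the compound's
experiments; compounds are compared by $d = 1 - r_{\text{Pearson}}$ and
agglomerated with the Ward criterion applied directly to that
precomputed, non-Euclidean distance (`hclust` method `"ward.D"`). Two
consequences are documented rather than hidden:

* Merge heights under this convention are implementation-relative, so an
  absolute dendrogram cutoff (the motivating analysis cut at 12) is only
  meaningful against the same linkage convention. The cutoff is exposed
  as a parameter, but the tested default is the automatic two-cluster cut
  (`k = 2`), which is what the planted-mechanism recovery checks use.
* Compounds are canonically ordered by id before clustering, so the
  result is invariant to input order; constant consensus vectors get
  correlation 0 (distance 1) with a warning rather than an error.

Cluster signatures are per-gene medians (midpoint interpolation for
even-sized clusters) ranked descending, and annotation delegates to the
preranked GSEA engine (default 1,000 permutations) with results ordered
by NES.

## 5. Cohort association

Associations are computed within cancer type, with both Pearson and
Spearman coefficients reported so no conclusion hangs on the linearity
assumption alone; types with fewer than 3 samples or constant inputs are
excluded with a recorded reason. Survival uses a single-covariate Cox
proportional-hazards fit (Efron ties) on the signature average — marginal
models only, matching how signature averages are interrogated — and a
log-rank test between the top and bottom score tertiles. Tertiles are
split as evenly as possible (sizes differ by at most one, remainder to
the lower groups) with tied scores assigned in input order to the lower
tertile first; this tie placement is stated because even splits on tied
scores are otherwise ambiguous. Degenerate fits (no events, constant
covariate, non-convergence) return flagged results with `NA` estimates.
Immune infiltration estimates are consumed as precomputed input columns;
deconvolution is out of scope. The survival endpoint is whatever column
the cohort supplies (progression-free interval or overall survival); the
package does not adjudicate between them.

## 6. What the synthetic conditions emulate — and what they do not

The generators are first-class, tested code, and their defaults *are* the
study conditions:

* `gen_paired_cohort()`: 20 + 20 patients (a paired anti-PD-1 melanoma
  cohort at evaluable size), 10,000 genes, 200 planted genes per
  direction with induced-change effect 1.5 noise SD. Pre-expression is
  baseline (log2 mean 7, SD 1) plus N(0, 1) noise; the induced change
  itself is N(effect·σ, σ²) on planted genes, N(0, σ²) elsewhere.
* `gen_perturbation_compendium()`: 2,000 genes, 200 compounds and 100
  shRNAs across 3 cell lines — sized so the full pipeline runs in
  minutes while preserving the screening structure. Profiles are standard
  normal; shifters add +γ on planted S genes and −γ on planted R genes
  (default γ = 2); mechanisms add +2–3 on disjoint 100-gene modules; TAS
  is Beta(6, 2) for active and Beta(2, 4) for inert perturbagens,
  encoding that the activity score tracks signal strength. The shRNA
  knockdown sets the target to −6 — deliberately below the −γ
  signature-wide suppression, because direct on-target knockdown is
  stronger than the indirect signature response, and a panel-relative
  percentile criterion can only recognize it if so.
* `gen_pancancer_cohort()`: 5 types × 100 samples, one latent immune
  factor per sample driving immune-signature genes and infiltration up
  and planted anti-immune targets down (loadings ±1), a second latent
  factor driving R-signature genes, and exponential survival with
  log-hazard β times the realized within-type-centered R-signature
  average (default β = 0.7) under independent exponential censoring
  (≈30%).

Noise is independent Gaussian per gene throughout: the downstream
statistics are rank- and threshold-based, so heavier tails would change
power but not correctness, and the generators expose the scale parameters
for users who want to stress that. What passing tests on these conditions
establish is that the *statistics and decision rules are implemented
correctly and are calibrated* (null false-positive rates near nominal,
null shift abilities centered at zero, planted structure recovered). What
they do not establish is performance on real cohorts: real expression has
correlated genes, batch structure, non-Gaussian noise, imperfect pairing,
and signatures whose effect sizes are neither uniform nor independent of
expression level. Headline numbers from the motivating analysis (signature
sizes of 1,190 R / 130 S genes, 780 shifting compounds, 49 concordant →
17 prioritized targets, specific AUCs and hazard ratios) require the
original external accessions and are not reproduced at this scale.

## 7. Problem sizes and runtime

The test suite and the acceptance script run the conditions above at
these sizes, chosen as the package's own reduced-scale defaults: 1,000
random instances for oracle equivalence of the enrichment score, 10,000
random profiles for the shift-ability bounds, 10 cohort seeds for
signature recovery, ≥ 500 null profiles for screen calibration, 40
compounds × 3 cell lines for mechanism clustering with 1,000
permutations for annotation, and n = 500–1,000 for survival calibration.
The orchestrated `run_pipeline()` at its default scale completes in
seconds and is byte-identical across reruns of the same configuration —
every output carries the configuration hash and seed in its header.

## 8. Known limitations

* GCT 1.3 and TSV are the supported matrix formats; HDF5-backed GCTX is
  not read (no HDF5 interface is bundled), so very large compendia must
  be converted upstream.
* The permutation null is gene-set permutation only; no
  phenotype-permutation GSEA on expression matrices is provided.
* Dose–response structure is ignored: each experiment is screened
  independently and aggregation is by perturbagen × cell line.
* Cox models are single-covariate and unstratified; competing risks are
  out of scope.
* The 130-vs-139 discrepancy in the published S-signature size of the
  motivating cohort is inherent to its description; with external data
  this package reports whatever the stated procedure yields rather than
  tuning to either count.
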