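---
title: "Deriving and validating blood DNA methylation episignatures"
author: "episignr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating blood DNA methylation episignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episignr)
```

## The problem

Pathogenic variants in chromatin-machinery genes leave reproducible genome-wide
DNA methylation patterns — *episignatures* — detectable in peripheral blood on
Infinium EPIC-style arrays. Once such a signature has been derived from a small
cohort of confirmed carriers and matched controls, it can classify variants of
uncertain significance (VUS): a carrier of a truly pathogenic variant shows the
signature, a benign variant does not. episignr implements the full workflow:
cohort preprocessing, differential-methylation probe discovery with a
three-stage selection funnel, an SVM-based *methylation variant pathogenicity*
(MVP) score, differentially-methylated-region (DMR) calling, and
genomic/chromatin-state enrichment — together with a synthetic EPIC-like cohort
generator that provides planted ground truth for every stage.

## The model

### Preprocessing

Beta values $\beta \in [0,1]$ (methylated fraction per CpG probe) are the
input; the package does not touch raw intensities. Probes flagged as
sex-chromosomal, cross-reactive, or SNP-overlapping are removed, and arrays
with strictly more than 5% failed probes are dropped (a sample at exactly 5%
is retained — the threshold is read literally as "more than"). For each case,
7 controls of identical sex minimizing $|\Delta \mathrm{age}|$ are selected
without replacement (8 cases yield 56 controls); cases are processed in
lexicographic id order with age ties broken by id, so matching is
deterministic and invariant to pool order. Propensity-score machinery is
deliberately not reproduced: sex and age are the only matching variables the
protocol names.

Testing happens on M-values $M = \log_2\!\frac{\beta'}{1-\beta'}$ with
$\beta'$ clipped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$
(standard variance stabilization; the clipping constant only matters at exact
0/1). Blood cell composition is a classic confounder: proportions are taken
from the sample sheet when present, otherwise estimated by non-negative least
squares against reference cell-type profiles and renormalized to the simplex.
One simplex column is dropped before entering the design so it stays full
rank.

### Differential methylation

Per probe, $M$ is regressed on an intercept, a case indicator, and the
covariates. The residual variances $s^2_g$ (df $d_g$) are shrunk by empirical
Bayes: the prior $(d_0, s_0^2)$ is estimated by the method of moments on
$\log s^2_g$ (Smyth 2004), the posterior variance is

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},$$

and the moderated $t$ has $d_0 + d_g$ degrees of freedom, with BH adjustment
across probes. The implementation is the package's own (one shared QR across
probes, Newton trigamma inversion for the moment equation); the test suite
cross-checks the hyperparameters against an independent uniroot moment solver
and the full statistics against limma on shared fixtures. When the observed
log-variances show no excess spread the moment estimator returns
$d_0 = \infty$ and every posterior variance equals $s_0^2$ — the
bias-corrected geometric mean of the observed variances, not the raw common
value, which keeps the estimator consistent with the scaled-F model.

Effect sizes are reported on the beta scale
($\Delta\beta$ = mean case $-$ mean control beta), because the "difference
greater than 10%" criterion is only meaningful there, while tests run on M.
DMPs require $|\Delta\beta| > 0.10$ **and** $q < 0.01$, both strict.

### The selection funnel

The published workflow describes 1000 candidates by the "interaction between
effect size and p-value", a ROC cut to 500, and removal of probes with
pairwise Pearson $r > 0.9$ — and simultaneously equates the final probe set
with the DMPs at the thresholds above. These are only consistent if the
funnel operates within the significant probes, and that is how
`episignature()` composes it:

1. candidate pool = DMPs (falls back to all probes, with a warning, when
   nothing is significant, so null-cohort analyses remain defined);
2. rank by $|\Delta\beta| \cdot (-\log_{10} p)$ (raw p by default; the
   adjusted p is a config switch), ties by smaller p then probe id, keep 1000;
3. per-probe ROC AUC via the Mann–Whitney rank-sum identity with midranks,
   rank by $\max(\mathrm{AUC}, 1-\mathrm{AUC})$ so hypo- and hypermethylated
   probes compete symmetrically, keep 500;
4. greedy correlation pruning in rank order: keep a probe iff $|r| \le 0.9$
   against every probe already kept (graph-optimal independent sets are not
   attempted; the greedy scan matches the described sequential removal and is
   deterministic). Constant probes have undefined $r$ and are kept with a
   warning.

ROC and pruning run on beta values; whether the original analysis used beta
or M there is not documented, and beta was chosen as the scale on which the
signature is later applied to new samples. The fitted object stores per-probe
case and control medians so new samples can be scored by concordance: a probe
is case-like when strictly $|B - \mathrm{control\ median}| >
|B - \mathrm{case\ median}|$; exact midpoints count as control-like.

### MVP classification

A linear-kernel SVM (e1071, the field's standard) is trained on
signature-probe betas with all cases against 75% of the controls and 75% of
each confounder cohort (stratified, seeded); the held-out 25% and any VUS
samples are only scored. Decision values are mapped to probabilities by a
Platt-type sigmoid fit on the training decision values. The calibration uses
raw 0/1 targets: with 8 cases, Platt's prior-smoothed positive target is
$(8+1)/(8+2) = 0.9$ exactly, which caps case scores at about 0.9, whereas
published MVP plots show saturated scores (cases near 1, background near 0).
Raw targets reproduce that behaviour on separable data; the smoothed variant
remains available (`platt_fit(smoothed_targets = TRUE)`). The classifier is
stored as plain numeric weights plus the two sigmoid coefficients, so models
serialize to JSON and round-trip exactly. The 0.5 score threshold labels
output rows only; the package never emits a clinical verdict.

Leave-one-out cross-validation re-derives the signature from the remaining
cases with freshly matched controls, embeds everything by classical
(Torgerson) MDS on the new signature, and assigns the held-out case to the
nearer group centroid — an algorithmic version of reading cluster membership
off an MDS plot.

### DMR calling

Probe-level statistics are aggregated by a transparent seed-and-extend rule:
runs of consecutive same-chromosome probes with inter-probe gaps
$\le 1000$ bp are candidates; a candidate is reported when it has $\ge 5$
CpGs, region-mean $|\Delta\beta| \ge 0.10$, and a BH-adjusted Fisher combined
p strictly below 0.01. The kernel-smoothing internals of dedicated DMR tools
are intentionally not reproduced — the three printed criteria are the
contract. Three reading choices were open and are fixed as follows: "within
1 kb" is the inter-probe gap inside a run; the 10% threshold applies to the
unweighted region mean (not each member); and "Fisher's multiple comparison
P" is BH across the size-eligible candidate runs (adjusting across every
1-probe run would make the stated threshold meaningless). Stouffer's combined
p (equal weights) is reported alongside; it requires p strictly inside (0,1),
so member p-values are clipped to $[10^{-15}, 1-10^{-15}]$ first.

### Enrichment

Gene-region enrichment contrasts signature probes against the analyzed
background per category with Fisher's exact test; the odds ratio is the
sample OR $ad/bc$ and the two-tailed p sums hypergeometric probabilities of
tables at the observed margins no more probable than the observed one.
Star tiers mirror the two published scales (probes: 0.01/10⁻³/10⁻⁶; regions:
0.05/0.01/0.001) and are annotations; a BH-adjusted q across categories is
reported alongside.

Region-level feature enrichment counts a DMR as hitting a category when
strictly more than 50% of its length is covered, and compares against
length-matched intervals placed uniformly at random (1000 draws, seeded) —
a documented empirical null replacing the internals of interval-tool Fisher
commands, whose exact margin construction is not recoverable from a methods
section.

Chromatin-state enrichment uses the combo score
$\mathrm{sign}(\ln \mathrm{OR}) \cdot |\log_2 \mathrm{OR}| \cdot
(-\log_{10} p)$ per reference epigenome and state. The 2×2 uses overlap
counts with the table completed to $N$ genomic "slots", where the slot width
is the **sum** of the mean query and mean reference interval lengths — the
span within which two intervals can touch. This choice is what centres the
score at zero under uniform random placement (using the mean interval length
instead biases the null OR upward); the indexing machinery of large-scale
interval search engines is not reproduced, only the score. State-wise score
distributions are compared by pairwise two-sided Wilcoxon rank-sum tests
(exact below a combined n of 50 without ties, otherwise the
continuity-corrected normal approximation with midrank tie correction) with
BH adjustment.

## The synthetic cohort generator

No patient data accompany the methodology, so validation runs on synthetic
EPIC-like cohorts with known planted truth. The generator's defaults define
the package's study geometry, mirroring the published design at desk scale:

| parameter | default | what it emulates |
|---|---|---|
| probes | 20,000 on 4 chromosomes | EPIC-scale array, desk-sized |
| cases / control pool | 8 / 200 | 8 carriers; pool from which 56 matched controls are drawn |
| confounder cohorts | 2 × 20 | other-disorder reference cohorts with unrelated signatures |
| signal probes / regions | 300 / 10 | planted differential probes; clustered region effects |
| planted $\Delta\beta$ | U(0.10, 0.20), 100% hyper | promoter-centred hypermethylation |
| logit noise sd | 0.15 | array-scale measurement + biological noise |
| cell types | 6, Dirichlet mixtures | blood composition, with a case shift so adjustment matters |
| epigenomes | 20 | chromatin-state reference panels (desk-scale stand-in for a 127-epigenome compendium) |

Probes are placed as CpG-island-like clusters (5–15 probes, 50–500 bp gaps)
plus isolated probes (2–20 kb gaps). Each cluster draws a category "theme"
from the configured marginal frequencies and members keep it with
probability 0.8, so per-probe category marginals equal the configured
frequencies exactly while clusters stay coherent enough to host promoter
DMRs. Baselines are bimodal (low mode ≈ 0.1 at promoter categories, high
mode ≈ 0.85 at Body/IGR). Samples are built as
$\beta = \mathrm{logistic}(\mathrm{logit}(\text{cell mixture}) +
\text{planted effect} + \mathcal{N}(0, 0.15))$: noise on the logit scale
keeps betas strictly inside (0,1) with the smaller variance near the
boundaries that arrays show. Planted offsets are calibrated per probe by
Gauss–Hermite quadrature so the *expected beta-scale* case-minus-control
difference equals the planted $\Delta\beta$ (a naive logit shift
under-delivers by a few thousandths at this noise level). Effects are only
planted where the baseline leaves headroom for the shift — which is also the
biology: hypermethylation happens at unsaturated, promoter-like probes — and
planted regions are fully affected clusters, so region means are not diluted
by unplantable members. Confounder signatures are disjoint from the case
signature and from each other, making specificity failures attributable to
the classifier. Synthetic epigenomes partition every chromosome into the
15-state vocabulary; promoter-themed clusters are covered by an Active TSS
segment (with flanks) in 85% of epigenomes, the rest of the genome is filled
with background segments dominated by the quiescent state.

What passing tests do *not* show about real data: the generator has no batch
or chip effects, no SNP-driven outlier probes, no relatedness among samples,
Gaussian logit noise rather than the heavier-tailed errors real arrays can
produce, and planted effects that are exactly coherent within regions. An
optional global background shift exists for the slight genome-wide
hypomethylation real carriers can show outside the signature, but its
magnitude is unquantified and the default is 0.

## Numerical choices and degenerate inputs

* p-values that underflow to 0 (moderated-t tails, Fisher combinations on
  extreme regions) are floored at the smallest positive double before BH.
* Ties are broken by (statistic, then probe/sample id) everywhere, so every
  stage is reproducible and order-invariant.
* `fisher_exact_2x2` treats $ad/bc$ with $bc = 0, ad > 0$ as $\infty$ and
  $0/0$ as undefined; the feature-enrichment wrapper maps the fully saturated
  table (identical hit profiles in both columns) to OR 1, i.e. no signal.
* Combo-score ORs offset zero cells by 0.5 (odds-ratio only; the p-value is
  exact).
* Wilcoxon comparisons with zero tie-corrected variance return p = 1.
* Problem sizes in the tests (3,000–20,000 probes, 10–20 seeds, 100k-rep
  Monte-Carlo nulls) were chosen as the smallest sizes at which the checked
  quantities stabilize.

## Limitations

The package consumes normalized beta matrices; IDAT parsing, background
correction, and methylation-based age/sex prediction belong to upstream tools
(minfi, wateRmelon). Gene-set enrichment against pathway databases is out of
scope. The MVP score is a statistical statement about similarity to a derived
signature, trained here against synthetic confounder cohorts rather than a
real multi-disorder reference database; a low score does not rule out
pathogenicity, and no numeric decision threshold is asserted beyond the
0.5 reporting label.
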