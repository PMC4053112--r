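---
title: "Cell-of-origin signatures and tumour classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-of-origin signatures and tumour classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosig)
```

This vignette is the package's own account of its statistical machinery:
the models, the defaults and why they were chosen, the numerical
conventions, and what the synthetic-data tests do and do not establish.

## The analysis in outline

The package relates sorted normal mammary cell subpopulations — basal,
stromal, nonclonogenic luminal (NCL), and three luminal-progenitor (LP)
subtypes (human: ALDH+, ALDH−, ERBB3−) — to breast-tumour expression
profiles. The chain is:

1. filter genes by across-sample variability;
2. rank genes for each pairwise cell-type comparison with a moderated t
   statistic and estimate q-values;
3. assemble signatures as unions of top up/down genes over all pairs and
   average expression per type into centroids;
4. score tumours against centroids by Pearson correlation (via
   unit-variance regression) and by joint mixture regression (partial
   correlations);
5. classify each tumour with a two-level nearest-centroid decision tree,
   optionally adding an intrinsic subtype from a user-supplied SSP table.

Two companion modules quantify the accompanying functional assays:
single-hit Poisson limiting-dilution analysis of repopulating-unit (MRU)
frequencies, and ΔΔCt relative quantification of qPCR plates.

## Variability filter

The pre-filter retains the `ceiling(keep_fraction * G)` genes of highest
across-sample variance (default `keep_fraction = 0.5`). It is deliberately
unsupervised — it never sees the cell-type labels — so it cannot bias the
subsequent differential-expression tests; it simply removes genes with no
information to contribute. The fraction is configurable because no single
value is canonical; 0.5 is a common middle ground for array-scale data.
Ties at the cut-off are resolved stably in favour of earlier input order.

## Moderated t, q-values and signature selection

For groups of sizes $n_A$, $n_B$ the per-gene pooled variance $s^2$ (with
$d = n_A + n_B - 2$ df) is shrunk towards a prior:

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d},
\qquad t = \frac{\bar x_A - \bar x_B}{\tilde s\sqrt{1/n_A + 1/n_B}},$$

with $p$-values from the t distribution on $d_0 + d$ df. The
hyperparameters $(d_0, s_0^2)$ are estimated from the ensemble of log
sample variances by moment matching under the scaled-F model, using the
digamma/trigamma relations; when the trigamma equation has no positive
solution the prior df is taken as infinite (variances fully shrunk). The
estimation can be overridden through `prior_df` / `prior_var`, which also
exposes the two analytic limits used as exact self-checks: `prior_df = 0`
reduces to the ordinary pooled t, `prior_df = Inf` to
$(\bar x_A - \bar x_B)/(s_0\sqrt{1/n_A + 1/n_B})$.

Ranking is by $|t|$. A log-posterior-odds statistic (`b_stat`, prior DE
proportion 0.01 by default) is also reported: for a shared design and
shared hyperparameters it is a monotone function of $t^2$, so the two
rankings coincide — the package tests this identity rather than assuming
it. The effect-variance ratio inside `b_stat` is estimated from the top
$t^2$ quantile by a moment argument; since it is shared across genes it
affects reported odds, never the ranking.

q-values follow the Storey construction with $\lambda = 0.5$:
$\hat\pi_0 = \min(1, \#\{p > \lambda\}/((1-\lambda)m))$, then
$q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. On small gene
sets the raw $\hat\pi_0$ can degenerate to 0 and annihilate every q-value,
so a floor of 0.05 is applied; forcing $\hat\pi_0 = 1$ recovers
Benjamini–Hochberg exactly, which the tests verify against
`p.adjust(..., "BH")`.

Signature selection takes up to `n_up` genes of largest positive $t$ and
`n_down` of most negative, each required to pass `q < fdr_cap` (default
0.05). The cap is applied *during* selection, so every selected gene is
FDR-significant; selection is supply-limited and an empty selection is a
legal outcome (an entirely empty signature union is an error at centroid
building). "Upregulated" means higher in the first-named group of a pair;
the pairwise union is orientation-symmetric.

## Centroids

A centroid is the per-gene arithmetic mean over a cell type's samples,
restricted to a signature. The first level uses four reference groups —
stromal, basal, luminal and the LP subtypes pooled as one group — with a
250/250 signature over the six pairwise comparisons; the pooled-LP
centroid is labelled `LP_combined`. Because the three LP subtypes are much
closer to one another than to anything else, their own centroids use a
dedicated 100/100 signature over the three LP pairs.

Two interpretation points were genuinely open and are recorded here as
package decisions (both configurable):

- the first-level "luminal" reference is the NCL population — it is the
  only mature (non-progenitor) luminal fraction, and the tree's four
  classes otherwise leave NCL unrepresented;
- `LP_combined` is built on the major (250/250) signature with the LP
  samples pooled as a single group, since it must be comparable with the
  other level-1 centroids on the same gene set.

Differential testing requires two samples per group; plain averaging
(`buildCentroid`) accepts one, matching what each computation needs. A
useful consistency property (tested): over a shared gene set, the pooled
LP centroid equals the sample-size-weighted mean of the LP subtype
centroids.

## Tumour scoring and the decision tree

"Scaled to unit variance" is implemented as full z-scoring (centre *and*
scale): the regression coefficient of one standardized variable on another
equals the Pearson correlation only when both are centred, and comparable
correlation-scale scores are the point of the scaling. For the same reason
the mixture regression of the z-scored tumour on all z-scored centroids is
fitted without an intercept — all inputs are already centred, so the
intercept is identically zero and omitting it simplifies the contract.

From each mixture coefficient's t statistic the partial correlation is
recovered through the exact identity $r_k = t_k/\sqrt{t_k^2 + \nu}$ with
$\nu = n_{\text{genes}} - K$. Both the standardized coefficients and the
partial correlations are returned, since they answer slightly different
questions (mixture weight vs adjusted association). Rank-deficient
centroid matrices are rejected with the collinear columns named.

Scoring uses the genes shared between tumour and signature, guarded by
`min_overlap` (default 0.5 of the signature): cross-platform gene loss
should fail loudly rather than silently degrade scores. Zero-variance
profiles over the shared genes are errors naming the profile.

The decision tree is a pure function of the score vectors: level 1 is the
argmax over {stromal, basal, luminal, LP_combined}; tumours routed to LP
get a level-2 argmax over the LP-subtype centroids *computed on the LP
signature*, which is where the subtypes are actually separable. Exact ties
are deterministic, not randomized: the fixed ascending priority order is
stromal < basal < luminal < LP (level 2: ALDH− < ALDH+ < ERBB3−), the
later label wins, and `tie_flag` is set so ties are never silent. The
direction of the priority is a convention; what matters is that it is
fixed, documented and flagged.

Intrinsic subtyping is the same nearest-centroid rule against a
*user-supplied* SSP centroid table (the package ships no subtype gene
list); a precomputed Claudin-low label, when present, passes through
untouched because that call is defined externally.

## Limiting dilution

Under the single-hit model, $P(\text{positive} \mid d) = 1 - e^{-fd}$.
The MLE of $f$ is obtained from a binomial GLM with complementary log-log
link and offset $\log d$ (intercept $= \log f$), iterated to convergence
tolerance $10^{-12}$. The default 95% interval is Wald on the
$\log f$ scale; a likelihood-ratio interval is available via
`ci_method = "lrt"`. Degenerate tables return bounds instead of failing —
all-negative: frequency 0 with the exact one-sided bound
$f_u = \ln 20 / \sum_i n_i d_i$; all-positive: a lower bound solving
$\prod_i (1 - e^{-f d_i})^{n_i} = 0.05$ — because real assays of
non-repopulating fractions (e.g. NCL cells) do produce all-negative
tables. Frequencies are also rendered as "1 in N" strings, the form in
which such results are conventionally reported. The MRU share of
population $i$ is $f_i n_i / \sum_j f_j n_j$.

The single-dose case has the closed form $-\ln(\text{fraction
negative})/d$, and the multi-dose MLE is checked against grid-search
likelihood maximization; simulated CI coverage at $f = 10^{-4}$ with doses
(5&#8239;000, 20&#8239;000, 100&#8239;000) and 6 transplants per dose sits
in the 93–97% band over 1000 seeded assays.

## ΔΔCt quantification

Replicate Cts are averaged (a warning flags replicate SD above 0.5
cycles); $\Delta Ct = Ct_{\text{target}} - \tfrac12(Ct_{hk1} + Ct_{hk2})$;
$\Delta\Delta Ct$ subtracts the comparator's $\Delta Ct$;
$RQ = 2^{-\Delta\Delta Ct}$. Averaging the two housekeeper Cts
arithmetically equals normalizing to the geometric mean of their
expression levels — the standard multi-reference-gene rule; the
combination rule and the no-template-control margin (default: any
amplifying NTC within 5 cycles of the earliest sample Ct fails the gene)
are package defaults, as no single convention is universal. Amplification
efficiency is fixed at 2 per cycle, the classic ΔΔCt assumption;
efficiency correction is out of scope. Two exact invariants are tested:
RQ is unchanged by a plate-wide Ct shift, and by swapping the two
housekeepers.

## Synthetic data: what it emulates, and what it does not

`genCellAtlas()` plants disjoint marker blocks on a flat baseline: each
non-LP type gets a block elevated by `major_effect`; the three LP subtypes
share one such block and are separated from each other only by
subtype-specific blocks at the weaker `lp_effect` — encoding the key
structural fact that LP subtypes are mutually closer than to any other
type. Samples add i.i.d. Gaussian noise. The defaults — 2,000 genes, six
human cell types, five samples per type, 50-gene marker blocks,
`major_effect` 2 log2 units (a 4-fold marker, typical of sorted
populations), `lp_effect` 1, `noise_sd` 0.5 — loosely mirror the scale of
a sorted-population array study and were fixed once as the package's
study conditions. `genTumorCohort()` draws each tumour as a convex
mixture with a dominant component (default weight 0.7, remainder spread
evenly) plus Gaussian noise at 0.25× the marker effect.

These generators satisfy the assumptions the inference makes
(homoscedastic Gaussian noise, exchangeable samples, genuinely convex
mixtures), which is exactly why they support calibrated recovery targets:
on the default cohort of 200 tumours the decision tree recovers the
dominant level-1 class with accuracy ≥ 0.90 and the LP subtype among
true-LP tumours with accuracy ≥ 0.80. What passing these tests does *not*
show: robustness to batch effects, bead-array technical artifacts,
correlated gene noise, overlapping marker programs, platform mismatch, or
tumour transcriptional programs absent from the normal reference — real
tumour cohorts violate all of these to some degree, and results on real
data should be read with that gap in mind.

## Numerical conventions and degenerate inputs

- Duplicate gene ids on load are collapsed by per-gene mean with a
  warning; missing or non-numeric cells are errors naming gene and sample.
- A gene constant within both groups has $s^2 = 0$; shrinkage with
  $s_0^2 > 0$ keeps its t finite, and the 0/0 case (zero fold change,
  zero variance) is defined as $t = 0$.
- Quantile summaries use R's default type-7 rule.
- GLM convergence tolerance $10^{-12}$; likelihood values that underflow
  far from the optimum are floored so interval searches stay defined.
- Generators are pure functions of their configuration including the seed;
  the pipeline stages write a JSON manifest (config, checksums) and
  re-running a stage with identical inputs is byte-identical, which the
  tests verify by file hash.

## Problem sizes used in the tests

The shipped tests run the full default atlas (2,000 genes × 30 samples)
once for the end-to-end recovery check and use a reduced atlas (400 genes,
20-gene blocks) elsewhere; limiting-dilution coverage uses 1,000 simulated
assays. These sizes give stable statistics while keeping the whole suite
fast enough to run habitually.

## Known limitations

- Single-factor two-group designs only: no covariates, pairing or array
  weights in the moderated t.
- No ortholog mapping: cross-species comparison means running the same
  pipeline on a mouse-labelled atlas (`mouseCellTypes()`); gene-id
  translation is the caller's responsibility.
- No expression normalization: inputs are assumed already log2-normalized.
- ELDA-style multi-group equality and goodness-of-fit tests, and qPCR
  efficiency correction, are not implemented.
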