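---
title: "Quantifying social integration from scan-sampling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social integration from scan-sampling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scansoc)
```

## The problem

Group-living primates differ strikingly in how well they are integrated
into their social group, and rearing history — in particular early
maternal loss and long-term social deprivation — is a prime candidate
explanation for those differences. A standard way to measure integration
in captivity is instantaneous scan sampling: at regular intervals an
observer records, for every adult, who is within an arm's reach of whom
(passive close proximity, a symmetric dyadic state) and who is grooming
whom (a directed behaviour). `scansoc` turns such records into weighted
social networks and asks, with a complete statistical pipeline, whether
individuals of different deprivation backgrounds occupy systematically
different positions in them.

Two weighted-network measures per individual carry the analysis:

* **Vertex strength centrality**, \(C_s(v_i) = s_i/(N-1)\), where the
  strength \(s_i\) sums the weights of the edges incident to \(i\)
  (out-edges in the directed grooming network) and \(N\) is group size.
  Because edge weights are percents of scans, \(C_s\) reads as the mean
  percent of scans spent within arm's reach of (or grooming) a group
  member, and lies in \([0, 100]\).
* **Deviation from edge weight disparity**. The disparity
  \(Y_2(v_i) = \sum_j (w_{ij}/s_i)^2\) measures how unevenly \(i\)
  spreads its weight over the \(N-1\) potential partners; it is
  \(1/(N-1)\) under an even spread and \(1\) for a single partner.
  Subtracting the group-specific even-spread value gives
  \(\Delta Y_2 = Y_2 - 1/(N-1) \in [0, 1 - 1/(N-1)]\), comparable across
  groups of different size: higher values mean more restricted partner
  choice. For an individual that never grooms, \(s_i = 0\) and the
  disparity is undefined; such rows are flagged and excluded listwise
  from disparity analyses (their strength centrality, 0, is kept). This
  exclusion is itself informative — a class in which few individuals
  groom at all contributes few disparity values.

Edge weights are \(w_{ij} = 100\,c_{ij}/n_{\mathrm{scans}}\) with
\(c_{ij}\) an integer scan count. All measures are computed on the
integer counts and divided late, so identities like the equal-spread
\(Y_2 = 1/(N-1)\) hold exactly in floating point, not merely
approximately.

## Statistical pipeline

Per behaviour (proximity, grooming given) and observation period, each
measure is modelled with a normal, identity-link mixed model: fixed
factors age class, sex, deprivation class and the sex-by-class
interaction; a random intercept for group. Models are fitted by maximum
likelihood (not REML) because the small-sample corrected AIC,
\(\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)\), is compared across
fixed-effect structures, which is only meaningful under ML; the selected
model is refitted by REML for coefficient reporting. Backward stepwise
selection drops, at each step, the single term whose removal lowers AICc
most, never removing a main effect while its interaction is retained
(marginality), and stops when no removal lowers AICc. Ties among
candidate drops are broken deterministically: higher-order terms first,
then alphabetically. Every candidate AICc at every step is kept in a
selection ledger.

Each fixed term is tested with a marginal (type-III-style) Wald F under
sum-to-zero contrasts, with denominator degrees of freedom \(n - p\)
(residual df, \(p\) the fixed-effect rank). This choice, rather than
Satterthwaite or containment approximations, keeps the second df equal
across terms of one model, which is how such analyses are conventionally
reported for this design. Because marginal tests differ from sequential
ones in unbalanced data, analyses fitted elsewhere with sequential sums
of squares may differ; this is a known divergence risk we accept and
document.

Post-hoc comparisons use the two-sided Mann–Whitney U test with the
\(U = \min(U_a, U_b)\) reporting convention. The p value is exact (from
the null distribution of U) whenever \(n_a n_b \le 400\) and there are
no ties, otherwise a normal approximation with tie and continuity
corrections is used. Three comparison families are run as the retained
terms dictate: all pairs of eligible deprivation classes (always);
female vs male when sex was retained; within-sex class pairs when the
interaction was retained. Holm–Bonferroni correction is applied within
each family per measure and period — the familywise unit is the set of
comparisons that one retained term licenses; a global correction across
measures and periods would be a different, defensible choice, but the
per-measure-per-period family matches how such results are reported and
read. Classes with fewer than `min_class_n` individuals (default 3,
chosen because a class of two admits no informative rank test) are
excluded from every family.

The random term deserves a note: grouping is by group identity. Group
size is constant within a group, so grouping by size and by identity
coincide unless two groups happen to share a size, in which case
identity is the defensible unit; `random_by = "group_size"` exposes the
alternative.

## The synthetic generator

Raw scan records from the motivating study system are not deposited, so
the package carries a first-class generator whose defaults encode the
study-like conditions: 41 adults in four groups — two newly formed
ex-laboratory-like groups of 9 (5 early long-term deprived, ELD, plus 4
late long-term deprived, LLD, each) and two stable zoo-like groups of 12
and 11 (4 + 8 and 3 + 8 early-maternally-deprived EMD / non-deprived ND,
with 27 females and 14 males split by class as in the study population)
— observed for 500 scans per group in each of two periods.

The generative model, per scan: dyad \((i,j)\) is in proximity with
probability \(\sigma_i\sigma_j\); each individual grooms with
probability \(\gamma_i\), directing the bout at one partner drawn from a
preference vector \(\pi_i\) realized once per individual from a
symmetric Dirichlet with total concentration \(\kappa_{c(i)}\).
Preferences are drawn once — not per scan — so partner selectivity is a
stable property of the individual, which is what the disparity measure
presumes. One partner per groomer per scan keeps grooming weights
interpretable as percents of scans.

Class defaults: \(\gamma\) = 0.05 (ELD), 0.20 (LLD), 0.20 (EMD), 0.35
(ND); \(\sigma\) = 0.08, 0.12, 0.35, 0.45; \(\kappa\) = 0.3, 1, 3, 30 in
the same order. Around the class values, each individual's \(\sigma_i\)
and \(\gamma_i\) are jittered on the logit scale with SD
`individual_sd = 0.8`. The heterogeneity term matters: animals of one
rearing background are not behaviourally interchangeable, and without
between-individual spread every class mean difference — including small
ones the study design should *not* resolve — would be detected with
near certainty at 500 scans. The value 0.8 was calibrated once, at
design time, so that the generator reproduces the qualitative class
pattern of interest (ELD lowest grooming strength; ND least selective
in grooming; ELD/LLD most selective in proximity) while leaving the
LLD–ND grooming contrast inside the noise, and was then frozen.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: temporal autocorrelation between consecutive
scans, dominance-rank dynamics, reciprocity in grooming, immature group
members, observer error, and group-level random effects. The last point
is deliberate: the default generator has no shared group effect, so
that under a null parameterization (all classes identical) class labels
are exchangeable and the post-hoc machinery's type-I error can be read
directly.

One structural caveat surfaced by the null analysis: grooming strength
centrality is *not* group-size-free under this behavioural model. A
grooming bout occupies one scan regardless of how many partners are
available, so dividing strength by \(N-1\) imposes a \(1/(N-1)\)
gradient on individuals in larger groups. With classes segregated into
different-sized groups (as in the default, study-like design) a naive
null simulation therefore shows spurious class differences. Null
simulations should use `null_group_specs()`, which interleaves all
classes through all four groups; under it the Holm-corrected
false-positive fraction is at the nominal level. For real data this
means grooming-centrality contrasts between classes housed in very
different group sizes partly reflect the standardization itself —
proximity centrality, whose expected value \(100\sigma_i\sigma_j\) per
partner is size-free, does not share the problem.

## Numerical and design choices

* Weights live on the percent scale (0–100); `w * n_scans / 100` is
  always an integer count by construction.
* Disparity uses exact integer counts; `Y2 = 1/(N-1)` is exact for an
  even spread, and the undefined case (`s_i = 0`) is `NA` plus a
  `defined` flag, never an error or a zero.
* The scan table is long/tidy (one row per event) with a `none`
  placeholder row for eventless scans so that the scan-count
  denominator round-trips through CSV. Proximity rows are accepted in
  either orientation and stored unordered.
* Individuals are assumed observable in every scan of their
  group-period; all logged scans count in the denominator, including
  scans with no recorded events.
* Singular random-effect fits (group variance at zero) are flagged, not
  raised — with four groups they are common and the fixed-effect
  inference under residual-df F tests remains usable.
* Terms whose design columns are dropped for rank deficiency are
  reported with 0 numerator df and `NA` F rather than silently omitted.
* AICc requires \(n > k + 1\); smaller analyses raise an informative
  error rather than returning an extrapolated criterion.

## Problem sizes used in the test suite

The packaged tests exercise the oracle equivalences on 100 random small
instances (up to 8 individuals, 50 scans), exact Mann–Whitney
enumeration for all sample-size pairs summing to 12 or less, parameter
recovery on 200 seeded runs and the null false-positive rate on 500
runs of the 41-individual design at 500 scans, and model selection on
200 simulated design tables of 40 individuals. These sizes were chosen
to estimate the relevant proportions to a few percent while keeping the
default test run comfortably interactive.

## Limitations

* The pipeline tests marginal (type-III-style) hypotheses; a
  sequential-test reanalysis of unbalanced data will differ.
* Mann–Whitney post-hocs ignore the group structure the mixed model
  accounts for; with classes nested in few groups they inherit whatever
  group confounding the design carries (see the group-size caveat
  above).
* The generator's dyadic-product proximity model cannot represent
  triadic closure or spatial constraints; class-graded selectivity in
  proximity arises only through heterogeneity and sampling noise, not
  through explicit proximity preferences.
* No permutation or node-swap null models are provided; the grouping
  structure is handled by the random intercept instead.
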