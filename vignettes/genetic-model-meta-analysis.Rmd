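---
title: "Pooling genetic association studies: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling genetic association studies: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genassocmeta)
```

## The problem

Candidate-gene association studies of a biallelic locus report, per
study, the genotype counts II / ID / DD among cases and controls (or,
when genotypes were not published, bare I / D allele counts). Individual
studies are usually small and their results disagree; the meta-analytic
questions are (i) what the pooled association is under each genetic
model, (ii) how much of the disagreement is genuine between-study
heterogeneity, (iii) whether the pooled picture is driven by particular
strata, particular studies, or small-study (publication) bias.
`genassocmeta` implements that entire pipeline on the summary-count
level; it never needs individual-level data.

## Per-study effect model

For one study and one genetic model the counts collapse to a 2×2 table
(a, b = exposed/unexposed cases; c, d = exposed/unexposed controls) and
the effect is the unadjusted log odds ratio with Woolf variance,

$$y = \log\frac{ad}{bc}, \qquad
  \widehat{se}^2 = \frac1a + \frac1b + \frac1c + \frac1d .$$

Only unadjusted ORs are used: published studies adjust for inconsistent
covariate sets, and mixing adjusted with unadjusted estimates would pool
incommensurable quantities.

The allele contrast counts 2N alleles per arm as if independent. Under
Hardy–Weinberg equilibrium (HWE) within each arm the two alleles of a
person *are* independent, so the Woolf variance is correct there; away
from HWE it is an approximation, which is one reason control-arm HWE is
checked (below) and flagged.

Zero cells receive the Haldane–Anscombe correction: 0.5 is added to all
four cells *of the affected table only*. This is the minimal standard
perturbation; correcting all studies would bias the many informative
tables to fix the few sparse ones. A table of four zeros carries no
information and is excluded with a diagnostic rather than corrected. The
constant is configurable (`meta_config(continuity = )`).

## Pooling and heterogeneity

Fixed-effect pooling uses inverse-variance weights $w_i = 1/se_i^2$.
Heterogeneity is quantified by Cochran's
$Q = \sum_i w_i (y_i - \bar y_w)^2$ on $k-1$ df and by
$I^2 = 100\,\max(0, (Q - df)/Q)$. The between-study variance is the
DerSimonian–Laird method-of-moments estimate

$$\hat\tau^2 = \max\Bigl\{0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\Bigr\},$$

and the random-effects pool re-weights by $w_i^* = 1/(se_i^2 +
\hat\tau^2)$. Conventions worth stating explicitly:

* The package always reports the random-effects result. When $Q \le
  k-1$, $\hat\tau^2$ truncates to zero and the result *is* the
  fixed-effect result, bit for bit — so homogeneous strata lose nothing
  and heterogeneous ones are handled honestly.
* The 95% CI uses the normal quantile 1.959964 on the log scale, with no
  small-sample (Knapp–Hartung) adjustment — matching the longstanding
  practice of the association-study literature this package serves, and
  keeping CIs comparable with published tables.
* $I^2$ is defined as 0 when $Q = 0$ and for $k = 1$, so single-study
  strata remain reportable.
* Significance of Q uses the liberal threshold $P(Q) < 0.10$ (the test
  is underpowered at typical k); $I^2$ bands read <25% as no/little,
  25–50% as moderate (boundaries inclusive), >50% as strong.
* REML is deliberately *not* used for pooling — the method-of-moments
  estimator is deterministic, closed-form and the de-facto standard for
  this literature — but is available in meta-regression as a cross-check.

## Hardy–Weinberg screening

Control genotypes are tested against HWE proportions $(1-p)^2$,
$2p(1-p)$, $p^2$ at the estimated allele frequency, a 1-df chi-square.
Departure in controls suggests genotyping error or population
stratification. A violation at `hwe_alpha` (default 0.05) **flags** the
record; it does not exclude it, because exclusion is a substantive
analysis decision that should not happen silently. Exclusion is available
as `meta_config(exclude_hwe_violations = TRUE)`. A monomorphic control
arm is treated as chi-square 0 (nothing testable at a fixed allele).

## Subgroups, meta-regression, trends, sensitivity

*Subgroups.* Pooling is re-run independently within each level of one
axis: ethnicity, study size (large/small at a configurable total-N
threshold, default 500, with the boundary classed "large"), intervention,
or treatment stratum. Missing axis values form an explicit `"unknown"`
subgroup, so subgroup k's always sum to the overall k. The size
threshold is user-settable because published large/small splits rarely
state their cut; any given split can be reproduced by adjusting it.

*Meta-regression.* One moderator at a time (published analyses report
per-covariate p-values, and k is rarely large enough for joint models),
weighted by $1/(se_i^2 + \hat\tau^2_{res})$. The residual $\tau^2$ uses
the method-of-moments generalization of DerSimonian–Laird by default;
`method = "reml"` maximizes the restricted likelihood with a
derivative-free golden-section search to interval tolerance 1e-10, with
an explicit check that the boundary $\tau^2 = 0$ is not better than the
interior optimum. Ethnicity is encoded Asian = 1 / Caucasian = 0; other
groups are dropped with a diagnostic rather than forced into an
arbitrary code. A constant moderator degenerates, by construction, to
the intercept-only model whose intercept equals the random-effects
pooled log OR.

*Cumulative meta-analysis* re-pools after each publication year (all
same-year studies enter together), using random effects at every step;
the final step equals the overall pool by construction, and the tests
assert it for all five genetic models.

*Leave-one-out* re-pools k times omitting each study in turn.

## Small-study bias

The funnel coordinates (log OR against precision 1/se) are emitted for
plotting. Two tests are provided:

* **Egger regression** — the original unweighted OLS of the standardized
  effect $y_i/se_i$ on precision $1/se_i$; the intercept is the
  asymmetry statistic, tested two-sided on $k-2$ df. A
  precision-weighted variant is available behind `weighted = TRUE`. At
  least 3 studies and non-identical standard errors are required (equal
  se makes the design singular).
* **Begg–Mazumdar rank correlation** — ties-corrected Kendall τ between
  the standardized deviations from the fixed-effect pool (with the
  pooled variance subtracted from each study variance) and the study
  variances, normal-approximation p without continuity correction.

The funnel-plot literature often labels its figures after Begg while
quoting Egger p-values in the text; this package exposes both and treats
the Egger p as the headline asymmetry number, because the regression
test is the one with an effect size (the intercept) attached. Neither
test has good properties below k ≈ 10; both are reported with their k.

## The synthetic-study generator

`simulate_studies()` provides the known-truth fixtures for every test:

* study-specific true effects $\theta_i \sim N(\log OR_{true}, \tau^2)$;
* control genotypes multinomial at HWE for allele frequency $p_D$;
* case genotype probabilities equal to the control probabilities tilted
  by $e^{\theta_i}$ per D allele, renormalized. This tilt keeps the
  cases exactly at HWE for the tilted allele odds, so the per-allele
  odds ratio at the allele-count level is *exactly* $e^{\theta_i}$ — the
  generator's truth and the estimand coincide, which is what makes
  calibration experiments meaningful.

Defaults emulate a realistic published restenosis cohort: 23 datasets,
arm sizes uniform over the printed range of such cohorts (cases 15–513,
controls 25–2572), years 1993–2012, follow-up within the 3–12-month
window, 60–90% male, High/Median quality labels. The metadata carry no
statistical weight unless used as moderators. An optional selection rule
mimics publication bias: a study whose allele-contrast p exceeds a
threshold is discarded and redrawn with a given probability, so the
returned collection keeps its nominal k while over-representing
significant results.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: confounding and covariate
adjustment differences between studies, linkage disequilibrium with
truly causal variants, genotyping error, overlapping case series,
population stratification within a study, and outcome-definition
drift. It validates the *statistical machinery*, not the epidemiology.

## Verification design

Every statistic has a second, independent route in the test suite:
DerSimonian–Laird pooling, Q, $I^2$ and the Egger OLS are checked on a
thousand random small instances (k ≤ 8) against flat textbook arithmetic
and `stats::lm`, and on further instances against `metafor`; Begg's
statistic is checked against exhaustive pairwise concordance counting
and `stats::cor.test`; the HWE chi-square against `stats::chisq.test`.
Calibration experiments use 300-replicate batteries at k = 20 studies of
~500 per arm (95% CI coverage under a true per-allele OR of 1.3, τ²
recovery under τ² = 0 versus 0.2) and 200-replicate null calibrations at
2000 per arm — sizes chosen to keep the whole suite in the low minutes
while leaving Monte-Carlo error well inside the asserted bands. All
simulations are seeded and reproducible.

## Known limitations

* Mantel–Haenszel fixed-effect pooling is not implemented (the
  inverse-variance framing is used throughout); at very sparse counts MH
  would be preferable.
* The five genetic models are correlated tests of one locus; no
  cross-model multiplicity correction is applied, matching field
  practice of reporting all five.
* Heterozygous/homozygous contrasts discard the excluded genotype class,
  so their arms do not sum to the full sample.
* No trim-and-fill or contour-enhanced funnel adjustment; the bias tests
  detect, they do not correct.
* Genotype imputation from allele counts is deliberately absent:
  allele-only studies are eligible for the allele contrast only.
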