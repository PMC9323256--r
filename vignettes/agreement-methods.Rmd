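---
title: "Methods: multi-rater agreement, concurrence, and the predictive tool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-rater agreement, concurrence, and the predictive tool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathagree)
```

## The study design this package models

Histopathological diagnosis is subjective: the same bladder section can be
read as cystitis by one pathologist and as normal tissue by another,
especially when the submission form carries no animal information. The study
design at the heart of this package puts a panel of four board-certified
veterinary pathologists in front of 25 canine and feline urinary bladder
slides (7 cystitis, 6 neoplasia, 6 urolithiasis, 6 normal by reference
diagnosis) under three *sequential* reading conditions — no animal
information, then signalment and clinical history, then a probability-based
predictive tool — and repeats the whole exercise on two media: digital
whole-slide images (WSI) and conventional glass slides (22 of the 25 blocks
were available for recutting). Each read yields one categorical diagnosis
per slide, rater, condition and medium, from the closed set *cystitis,
neoplasia, urolithiasis, normal, other*.

The package provides every statistical stage of such a study: planning
(sample size), agreement (Fleiss and Cohen kappa), concordance with the
reference diagnosis (concurrence, sensitivity, specificity), the predictive
tool itself (a multinomial-logistic probability calculator), imputation of
missing ratings, and a synthetic-study generator used for validation,
because per-slide ratings of the motivating study were never deposited —
only its marginal count tables, which the bundled fixture reproduces
exactly.

## Agreement statistics

### Fleiss kappa

For $n$ subjects each rated by $m$ raters into $k$ categories, with $n_{ij}$
the number of raters placing subject $i$ in category $j$:

$$p_j = \frac{\sum_i n_{ij}}{nm}, \qquad
P_i = \frac{\sum_j n_{ij}^2 - m}{m(m-1)}, \qquad
\bar P = \frac{1}{n}\sum_i P_i, \qquad
\bar P_e = \sum_j p_j^2,$$

$$\kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e},\qquad
\kappa_j = 1 - \frac{\sum_i n_{ij}(m - n_{ij})}{nm(m-1)\,p_j q_j},\quad q_j = 1 - p_j.$$

A category that is never (or always) used has $p_j \in \{0, 1\}$ and no
defined $\kappa_j$; `fleiss_kappa()` reports it as `NA` and the report
layer omits the row with a note, rather than zero-filling. If **all**
ratings fall in one category, $\bar P_e = 1$ and the overall statistic is
undefined; this is an error, not a silent `NaN`.

Significance uses the large-sample *null* standard errors (the classical
multi-rater forms): per category $\mathrm{se}_0(\kappa_j) =
\sqrt{2 / (nm(m-1))}$ and overall

$$\mathrm{se}_0(\kappa) = \frac{\sqrt 2}{\sum_j p_j q_j \sqrt{nm(m-1)}}
\sqrt{\Big(\sum_j p_j q_j\Big)^2 - \sum_j p_j q_j (q_j - p_j)},$$

so $z = \kappa/\mathrm{se}_0$ and the two-sided normal $p$-value test the
hypothesis of purely chance agreement. A jackknife variance would be the
main alternative; the null-variance form is the package default because it
is the textbook companion of the statistic and reproduces the familiar
"kappa, z, p" table layout.

Interpretation bands follow the conventional rule: below 0.40 *poor*, 0.40
to 0.75 *fair to good*, above 0.75 *excellent*. Both cut points are
inclusive to the middle band; the literature's "below 0.40 or so" leaves
the boundary vague, and an inclusive middle band means a study that lands
exactly on a threshold is given the more moderate label.

Worth knowing when simulating: the estimator has a small negative
finite-sample bias under independent random rating, approximately
$-1/(nm-1)$ (about $-0.01$ for a $25 \times 4$ panel), so the *mean* kappa
of null simulations sits just below zero rather than at it.

### Confidence intervals by subject-level bootstrap

The motivating design reports kappa with 95% intervals but no interval
method. `bootstrap_kappa_ci()` resamples *subjects* (slides) with
replacement — the slide set is the sampling unit; the rater panel is fixed
by design — recomputes the overall kappa per resample, and takes percentile
quantiles; the default is 2000 replicates. Degenerate resamples (all
ratings in one category) are skipped and counted, and more than 50% skipped
is an error. Coverage is validated in the test suite against
common-correlation (beta-binomial) panels with a known population kappa.

### Cohen kappa and concurrence

Concurrence — the study's term for accuracy against the reference
diagnosis — pools slide-by-rater pairs: the proportion of pairs whose
diagnosis matches the reference, with

* exact Clopper–Pearson 95% limits (`binom.test`),
* a one-sided exact binomial $p$-value against the *no-information rate*,
  the largest reference-class share among retained pairs (the design's
  tables do not say what their concurrence $p$-values test against; testing
  against the no-information rate is the confusion-matrix convention this
  package adopts and documents, without claiming it is what the original
  analysis did), and
* an unweighted Cohen kappa between the pooled ratings and the replicated
  reference, with the Fleiss–Cohen–Everitt null variance for its $z$ and
  $p$. The original tables do not name their estimator; unweighted Cohen
  kappa on (rating, reference) pairs is the natural companion of the
  concurrence framing.

Because a diagnosis of 'other' cannot be scored against a reference that
never contains it, `remove_other()` removes — within each condition-medium
stratum — every slide on which *any* rater chose 'other'. Dropping the
whole slide rather than one rater's record keeps the panel balanced for
kappa; the removal counts are logged on the returned table. The rule is
idempotent, and emptying a stratum entirely is an error naming the stratum.

Sensitivity and specificity are one-vs-rest over the same pooled pairs;
zero denominators yield `NA`, never 0.

## The predictive tool

The tool is a multinomial logistic model of the collapsed diagnosis on six
histological variables: species, urothelial ulceration, submucosal lymphoid
aggregates, neutrophilic submucosal inflammation, urothelial inflammation,
and the amount of submucosal hemorrhage (mild / moderate / severe,
treatment-coded with mild as baseline). Normal and 'other' are pooled into
the baseline outcome class `normal_other` — both are individually rare, and
the original tool was built the same way — so the model predicts

$$P(y = c \mid x) = \frac{e^{x^\top\beta_c}}{1 + \sum_{c'} e^{x^\top\beta_{c'}}},
\qquad c \in \{\text{cystitis}, \text{neoplasia}, \text{urolithiasis}\}.$$

`fit_diagnosis_model()` maximizes the multinomial log-likelihood by Newton
iteration with step halving. On quasi-separation (diverging coefficients or
non-convergence) it refits with a small ridge penalty, default $10^{-4}$,
and records the penalty in the fitted object — separation is a real risk at
the 338-case scale such tools are fitted at, let alone smaller. The
coefficient covariance is the inverse observed information at the optimum.
The fit is verified in the test suite against an independent multinomial
fitter (`nnet::multinom`) to four decimals.

Probability confidence limits use the delta method: for class probability
$p_c(x)$, the gradient w.r.t. the stacked coefficient vector is
$g_{c'} = p_c(\delta_{cc'} - p_{c'})\,x$, the variance $g^\top \Sigma g$,
and normal-theory limits are clipped to $[0,1]$. The delta half-widths are
validated against a 10,000-draw parametric simulation from
$N(\hat\beta, \Sigma)$.

Design choices worth recording:

* **Species.** One joint model with a species indicator is the default
  (fewer parameters at realistic fitting sizes); `species = "stratified"`
  fits two independent per-species models, matching a workflow that keeps
  separate canine and feline worksheets. Either way
  `enumerate_lookup()` emits one table per species: $2^4 \times 3 = 48$
  rows, binary features most-significant-first, hemorrhage fastest.
* **Hemorrhage levels.** The tool's answer sheet offers only
  mild/moderate/severe, with no "none" — presumably raters mapped absent
  hemorrhage to "mild", but that is unknowable from the published design.
  The default encoding implements the sheet as printed; a 4-level set
  including `none` can be configured via `feature_encoding()`.
* **Ties.** When two classes share the maximal probability the tool
  displays both; it never auto-diagnoses. The human is prompted to make the
  diagnosis; the tool only shows probabilities.

A caution on validation scale: with 24 free parameters, the standard errors
of the enumerated per-class probabilities at $n = 2000$ fitting cases are
roughly 0.02–0.05 (largest at design corners), so the maximum deviation of
a refit from its generating probabilities across all 48 combinations is
typically 0.08–0.11 at that size. Recovery checks in the test suite are
therefore expressed in units of the delta-method standard error where a
seed-robust assertion is needed.

## Imputation of missing ratings

One rater could not read part of the digital slide set; the design's remedy
is chained-equation imputation with a polytomous (multinomial logistic)
model, the standard treatment for unordered categorical missingness.
`impute_ratings()` pivots the table wide by rater (one row per
slide-condition-medium), and for each incomplete rater column repeatedly
fits a multinomial model of that column on the other raters'
observed-or-currently-imputed diagnoses plus condition indicators, then
draws each missing cell from its predicted category distribution. Defaults
are $m = 5$ completed datasets and `maxit = 10` sweeps (the design states
neither; these are the conventional chained-equation defaults). Each fit
uses a bootstrap resample of the complete rows as an approximate parameter
draw, making the imputation "proper"; `proper = FALSE` gives plain
maximum-likelihood draws. Imputation is performed jointly across conditions
within a medium, with condition as a predictor — whether the original
analysis imputed within or across conditions is unstated; pooling borrows
strength from the rater's own behaviour under the other conditions.
Degenerate component fits (single observed category, rank deficiency,
optimizer failure) fall back to draws from the column's observed empirical
distribution, and every fallback is logged.

Observed cells are never modified; chain $i$ is seeded with `seed + i`, so
results are reproducible. Downstream kappas computed on the $m$ completed
sets are pooled by Rubin's rules (`pool_kappa()`): mean point estimate,
within-variance plus $(1 + 1/m)$ between-variance. The report layer pools
kappas this way; concurrence and sensitivity/specificity are computed on
the first completed set, since a handful of imputed cells barely move a
pooled proportion while the kappas are the study's primary endpoint.

## Sample-size planning

`kappa_sample_size()` returns the smallest $n$ whose expected lower
one-sided $100(1-\alpha)\%$ confidence limit,
$\kappa_0 - z_{1-\alpha}\sqrt{\mathrm{Var}(\hat\kappa)}$, reaches the
assurance floor $\kappa_L$, searching upward from $n = 2$. Two variance
models are offered:

* `"pairwise"` (default): the classic large-sample variance of the binary
  intraclass kappa,
  $\mathrm{Var} = \tfrac{1-\kappa}{n}\big[(1-\kappa)(1-2\kappa) +
  \kappa(2-\kappa)/(2pq)\big]$. It prices the study on the agreement
  information carried by rater *pairs* and is deliberately conservative for
  larger panels (the rater count is validated but does not shrink the
  variance). With $\kappa_0 = 0.5$, $\kappa_L = 0.2$, $\alpha = 0.05$,
  prevalence $0.5$ this gives $n = 23$ — the case count the motivating
  four-rater study was planned to.
* `"information"`: the inverse expected Fisher information of
  $(\text{prevalence}, \kappa)$ under the Dirichlet-multinomial
  common-correlation model with $m$ ratings per subject. This is the
  statistically efficient multi-rater answer — it shrinks as raters are
  added (the same configuration gives $n = 10$ at $m = 4$) — and is the
  right choice when every rater's reads genuinely contribute independent
  information.

The pairwise criterion is the default because planning conservatively on
pairwise information is defensible whenever raters share systematic reading
habits, and because it reproduces the planning arithmetic of the study this
package is built around. All four inputs are explicit arguments, so either
convention is one call away.

## The synthetic generator and the fixture

`simulate_study()` emulates the full design. Its **defaults are the study
conditions**: 25 slides in the published 7/6/6/6 class split with the
published canine/feline mix per class, four raters, three conditions, both
media (glass missing three neoplasia blocks), and 20% missingness for rater
P4 on the digital medium. Rater behaviour is a *confusion kernel* per rater
and condition: a row-stochastic matrix from true diagnosis to reported
diagnosis including 'other'. The default kernels put the confusion mass
among cystitis / urolithiasis / normal (their histology genuinely
overlaps), recognise neoplasia well, and order the base accuracies
no-information (0.55) < signalment/history (0.65) < predictive tool (0.75)
with small per-rater offsets — the qualitative pattern the sequential design
is meant to produce, with magnitudes chosen once as plausible for this
panel. Per-class feature distributions give inflamed bladders inflammation
features and keep normal bladders mostly clean; perceived feature answers
add per-rater flip noise (default 0.1).

What the generator does **not** model: within-rater memory across
conditions and media (each read is drawn independently given the truth,
whereas real pathologists remember their previous answer), slide-level
difficulty shared across raters beyond the true class, free-text behaviour,
and any image-quality effect of digitization. Passing tests on simulated
panels therefore validate the *statistics*, not claims about real
pathologist behaviour.

`fixture_study()` is deterministic, not simulated: a greedy
constraint-satisfying assignment that visits slides in id order and gives
each slide the first still-available category from a reference-specific
preference list (reference diagnosis first, confusable categories next).
Its per-rater, per-condition marginal counts equal the published WSI and
glass count tables cell for cell; the per-slide patterns are synthetic, and
every shipped fixture file says so in a header comment. Two printed cells
required reconciliation: the digital predictive-tool column of the
incomplete rater sums to 19 although its printed total row says 17 (the
cells are taken as authoritative), and one glass signalment/history column
sums to 18 against a printed total of 22 (its normal-category cell is
raised from 0 to 4, the only single-cell correction consistent with the
column total and the rater's normal counts under the adjacent conditions).
Because only marginals survive in print, the fixture cannot — and does not
claim to — reproduce the study's published kappa or concurrence values,
which depend on the per-slide rating patterns.

## Numerical conventions and test scales

* Kappa formula vs brute-force pairwise-agreement oracle: tolerance
  $10^{-12}$ on 1000 random small panels ($n \le 6$, $m \le 4$, $k \le 3$).
* Degenerate inputs error loudly: single-category panels, unequal row sums,
  empty strata, a reference that fails to cover a rated slide (named), a
  rater column with no observations.
* Bootstrap: 2000 replicates by default; 200–500 in tests, which keeps the
  full suite under half a minute while the coverage check (500 panels,
  replicates 400) still resolves the nominal rate.
* Simulation scales used by the validation suite: 200 replicate studies for
  the condition-ordering check; 2000 panels for the null-kappa check;
  $n = 2000$ cases for tool-recovery checks; imputation recovery on a
  60-slide high-agreement panel at 20% missingness with $m = 20$.
* All randomized routines take an explicit integer seed and restore the
  caller's RNG state.

## Known limitations

* The agreement layer covers unordered categories only — no weighted kappa,
  Krippendorff alpha or Gwet AC1; diagnoses are categorical, so no ROC.
* The original tool's coefficients lived in a hidden worksheet fitted to a
  338-case collection that was never published; this package re-implements
  the model *form* and fits it to user or synthetic data, it does not
  recover the original coefficients.
* Rubin pooling is applied to kappa on its raw scale; for kappas near the
  boundary a variance-stabilizing transform would be preferable.
* The concurrence $p$-value convention (vs the no-information rate) is a
  package choice, documented above, not an inference about what the
  original analysis tested.
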