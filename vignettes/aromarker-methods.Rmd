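---
title: "Methods: odor-activity profiling and origin discrimination of tea volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-activity profiling and origin discrimination of tea volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromarker)
library(dplyr)
```

aromarker implements a complete analysis pipeline for volatile-compound
profiles of green tea (or any comparable product) sampled across growing
regions and quality grades: semi-quantification, odor-activity scoring,
composition and presence analysis, chemometric discrimination, and marker
selection. This vignette explains the models and procedures, the choices
made where the methods literature leaves options open, and what the
package's synthetic data can and cannot tell you about real data.

## The data model

The central object is a long tibble with one row per compound × sample.
Samples are region–grade pairs (e.g. `HY-S` is the standard-grade batch
from the Huangyan region); each cell carries a mean concentration in μg/L
and a standard deviation over replicate injections (three by default), or
is *censored* (`n.d.`) when the signal fell below the detection criterion.
Censoring is all-or-nothing at the cell level — the source tables publish
either a mean ± SD or `n.d.`, never partial replicates — and the package
treats blank cells as `n.d.` since the format distinguishes no third state.

```{r}
peaks <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
count(peaks, detected)
```

The packaged table covers 66 volatiles in 8 samples (4 regions × 2
grades). Its chemical-class labels follow the seven-category scheme usual
for tea volatiles (terpenes, aldehydes, alcohols, esters, ketones,
heterocyclics, others). The aroma-category labels (floral, woody, green,
fruity, malty, roasty, other) are an editorial assignment made for this
package from common descriptor usage; composition profiles by aroma
category therefore illustrate the method rather than reproduce any
published figure.

## Semi-quantification and retention indices

Concentrations come from single-point internal-standard calibration,
$C_i = (A_i / A_{IS}) \cdot C_{IS}$, with 2-octanol as the internal
standard. For the tea protocol (5 μL of 5 μg/mL standard into 10 mL of
infusion) the effective $C_{IS}$ is 2.5 μg/L; the constant is an argument,
not a hard-coded value, because the dilution arithmetic belongs to the
experiment, not the method. No response-factor correction is applied —
the upstream method is semi-quantitative by design.

Retention indices use the van den Dool–Kratz (temperature-programmed)
form against a C7–C40 n-alkane ladder:
$LRI = 100n + 100\,(rt - t_n)/(t_{n+1} - t_n)$. The index is
piecewise-linear, continuous and strictly monotone over the ladder span.
Analytes eluting before the C7 alkane are labelled `"<700"` rather than
extrapolated: extrapolation outside the homologous series has no
validated meaning. `retention_index_label()` implements that reporting
convention.

## Odor activity values

A volatile's perceptual contribution is scored by its odor activity
value, $OAV_i = C_i / OT_i$, concentration over the olfactory threshold
in water. Raw OAVs are kept at full precision; *reported* values follow
the conventions of published OAV tables — censored cells report `n.d.`,
raw values below 1 report `"<1"`, and everything else is rounded half-up
to an integer (`round_half_up()`, because base R's round-half-to-even
would turn 0.5 into 0).

The activity screen keeps compounds whose **maximum raw OAV over
samples strictly exceeds 1**. The methods convention is sometimes stated
as `≥ 1` and sometimes as `> 1`; on the packaged table both give the same
18 compounds, and the strict form is used because it makes the screen
monotone in the threshold with no boundary ambiguity. Fold ranges
(max/min raw OAV over detected samples) and grade contrasts
(premium/standard fold ratio, percent decrease from standard) likewise
use raw values and round only for reporting.

One reporting caveat found while validating against the published table:
a single integer cell (β-ionone in SX-S) cannot be reproduced from the
printed two-decimal concentration — 4.42/0.021 rounds to 210, the table
prints 211, and only an unpublished third decimal separates the two. The
acceptance tests therefore compare each printed integer against the set
of values reachable from concentrations consistent with the printed
precision.

## Chemometrics

**Preprocessing.** Censored cells enter the data matrix as 0 and every
column is autoscaled (mean 0, unit variance). Autoscaling is the standard
choice for concentration matrices spanning orders of magnitude, and
imputing censored cells to 0 is the only treatment coherent with the
all-or-nothing censoring model; columns constant across samples are
dropped with a warning since they carry no scaled information.

**PCA** is computed by singular value decomposition of the centered
matrix; explained-variance fractions are the covariance eigenvalue
ratios. **HCA** uses Euclidean distances with Ward (default), average or
complete linkage. Both are checked in the test suite against independent
oracles (a direct eigendecomposition; a brute-force Lance–Williams
agglomeration). Published variance percentages for comparable data
(around 35%/23% for GC-MS profiles) depend on unstated preprocessing, so
they are not exact targets; the packaged table yields 31.6%/24.5% under
the choices above.

**PLS-DA** is fit by NIPALS on the centered one-hot class matrix: per
component, the weight vector is iterated to convergence (tolerance
1e-10 on the change in the unit-norm weights), scores $t = Xw$, loadings
$p = X't/t't$, $q = Y't/t't$, and both blocks are deflated before the
next component. The default number of components is (classes − 1), the
rank bound of the centered response. The iteration cap is 10,000: the
power iteration's convergence rate is the ratio of the top two
eigenvalues of $FF'EE'$, and balanced multi-class designs routinely
produce nearly tied leading directions for which a few hundred
iterations are not enough; non-convergence is still an error, reported
with the iteration count. Weight and loading columns are sign-fixed so
the largest-magnitude entry is positive (ties to the lowest index),
making scores, loadings and plots reproducible.

**VIP scores** pool all response columns and components:
$VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SSY_a}$
with $SSY_a = (q_a'q_a)(t_a't_a)$. VIP variants differ between software
packages; this multi-response form satisfies $\sum_j VIP_j^2 = p$
exactly, which the tests verify across random designs. No cross-validated
$Q^2$ or permutation diagnostics are computed — they belong to model
validation workflows outside this package's scope.

## Marker selection and grade contrasts

Candidate origin markers must pass both screens: VIP > 1 (discriminative)
and maximum raw OAV > 1 (aroma-active), both strict, both on raw values.
The screen is only defined for compounds with a known odor threshold, so
the pipeline restricts it to the threshold-covered set. On the packaged
data the screen selects eight compounds — β-cyclocitral, geraniol,
indole, α-pinene, (Z)-jasmone, linalool, dimethyl sulfide and α-ionone —
which contains the published seven-marker set plus α-ionone; exact
agreement is not expected because the published model's preprocessing and
component count are unreported.

Duncan's multiple range test assigns letters after a one-way ANOVA: the
least significant range for a span of $p$ ordered means is
$R_p = q^*(\alpha_p, p, df)\sqrt{MS_E/n}$ with protection levels
$\alpha_p = 1-(1-\alpha)^{p-1}$, studentized-range quantiles from
`qtukey`, and the harmonic mean $n$ when replicate counts differ (with a
warning). Letters are assigned to maximal non-significant runs of the
descending-sorted means. Because published tables give mean ± SD (n)
rather than replicates, `duncan_letters_from_stats()` recovers the pooled
error mean square from the per-group SDs — algebraically identical to
the replicate-level path, which the tests confirm. Calibration: with two
groups the span-2 range test operates at level α exactly (the null
simulation in the test suite confirms ≈ 0.05 over 1000 datasets); with
more groups the familywise false-separation rate tracks Duncan's
protected level $1-(1-\alpha)^{k-1}$, while the rate for *adjacent*
ordered means sits well below α because adjacent order statistics are
stochastically close — a property of the procedure, not a defect.

## E-nose features

Metal-oxide sensor traces rise rapidly and then plateau; the package
summarises each sensor by its mean response over the stable window
(default 30–60 s). The mean is preferred to the maximum for noise
robustness, and no baseline subtraction is applied by default because the
instrument protocol regenerates sensors with a clean-air purge rather
than baseline arithmetic (both choices are arguments). `rise_fraction()`
verifies the rise phase, e.g. that the signal reaches 85% of maximum by
30 s. No published sensor values are reproduced — raw E-nose data are
not public — so all E-nose tests run on synthetic traces
$r_s(t) = R_s(1 - e^{-t/\tau})$ plus Gaussian noise, with τ = 8 s so the
trace reaches ~98% of its plateau by 30 s.

## Synthetic data: what it emulates, and what it does not

`generate_peak_table()` draws replicate concentrations lognormally around
region- and grade-adjusted baselines (lognormal because concentrations
are positive and replicate CVs in real tables are roughly scale-free),
moment-matched so the expected replicate mean equals the true cell
concentration at the requested CV (20% by default, the magnitude seen in
the packaged table). Cell means below the detection limit are censored to
`n.d.` — on the mean, not per replicate, mirroring the all-or-nothing
cells of real tables. All generators are pure functions of (config,
seed).

The marker-recovery experiments in the test suite use 40 compounds, 5
planted markers at a 4× region effect, replicate CV 0.15, and an
odor-threshold design under which 12 of 40 compounds are aroma-active —
matching the ~27% active fraction of the real table (18 of 66) so that
the OAV gate is realistically selective rather than trivially permissive.
PLS-DA runs on the 24 replicate-level rows (8 samples × 3 replicates)
when replicates exist, which is the granularity that keeps the
within-group variance in the model.

What the generator does *not* emulate: correlated compounds (biosynthetic
pathways co-regulate whole terpene families), chromatographic co-elution,
batch drift within a run, or heavy-tailed contamination. Passing the
recovery tests therefore shows the screen works when effects are
multiplicative, independent and lognormal — real data can violate all
three, and marker lists from real studies should always be inspected
against the concentration table, as the grade-contrast output encourages.

## Numerical conventions

* Rounding for reporting is always half-up (`round_half_up()`); raw
  values are never rounded internally.
* NIPALS: tolerance 1e-10, cap 10,000 iterations, error on
  non-convergence; sign convention as above.
* Autoscaling drops constant columns with a warning; an all-constant
  matrix is an error.
* The fixture analyses in the tests run in well under a second; the
  property suites (100 VIP fits, 50 synthetic screens, 2 × 1000 Duncan
  null datasets) complete in about a minute on one CPU — sizes chosen to
  put Monte-Carlo error well inside the asserted tolerances.

## Reproducing the table analysis

```{r}
out_dir <- tempfile("aromarker-")
smry <- suppressWarnings(run_pipeline(
  aromarker_example("tongcheng_peak_table.csv"),
  aromarker_example("tongcheng_odor_thresholds.csv"),
  out_dir
))
str(smry[c("n_active_compounds", "shared_core", "presence_counts",
           "selected_markers")])
```

Every number above is recomputed from the packaged tables at run time;
`scripts/acceptance.R` in the source repository writes the same headline
statistics as JSON.
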