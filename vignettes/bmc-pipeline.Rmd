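---
title: "Benchmark concentration analysis for plate-based zebrafish embryo screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark concentration analysis for plate-based zebrafish embryo screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmcscreen)
```

## The problem

Zebrafish embryo screens expose one embryo per well of a 96-well plate to a
concentration series of a test substance for five days, scoring mortality at
24 and 120 hours post fertilization (hpf) and phenotypic alterations in
survivors at 120 hpf. Different laboratories use different in-house
protocols (chorion on or off, static or daily-renewed exposure media,
different strains and phenotype scoring systems), which shifts both the
activity calls and the apparent potency of the same substances. Comparing
results across such labs needs three things: a harmonized representation of
the raw well records, a potency estimate that does not depend on each lab's
dose spacing, and summary statistics of cross-lab agreement. This package
provides all three, plus a synthetic study generator so the whole chain can
be validated against known ground truth.

## Endpoints and the data model

Each well record carries two mortality flags (24 and 120 hpf; death is
monotone in time by contract) and a possibly empty set of lab-specific
phenotype terms, scored only in viable embryos. Three incidence endpoints
are derived per plate, substance and concentration:

* `Mortality@24` — fraction dead by 24 hpf,
* `Mortality@120` — fraction dead by 120 hpf,
* `MalformedAny+Mort@120` — fraction dead *or* showing at least one
  recorded alteration ("affected").

The affected sets are nested, so the three response curves are ordered at
every concentration; `derive_endpoint()` warns (or errors, in strict mode)
when recorded data violate this.

Lab-specific phenotype terms are harmonized through a flat vocabulary into
six classes (edema, craniofacial, axis, trunk, pigment, other). The bundled
default vocabulary covers the term lists of three screening laboratories
with very different scoring systems; matching is case-insensitive, and in
lenient mode unknown terms fall into `other` with a warning rather than
failing a whole data delivery. Only the presence of *any* alteration feeds
the composite endpoint, so class granularity beyond the six required
classes is deliberately not modelled.

## Plate-level quality control

A plate is acceptable when at least 80% of its 12 vehicle-control embryos
(0.5% DMSO) survive to 120 hpf; survival of exactly 80% passes. Failing
plates are excluded (and logged with a reason code in the run manifest)
rather than corrected — in the originating study design such tests are
repeated, not imputed. A separate 20% response line is reported for
vehicle-control summaries but never discards data; it is a surveillance
threshold, not a QC rule.

## The benchmark concentration procedure

Each plate's concentration–response series is analysed independently:

1. **Bootstrap.** `n_boot` (default 1000) simulated curves are drawn; the
   incidence at concentration $i$ is resampled as
   $\mathrm{Binomial}(n_i, x_i/n_i)$ and converted to percent response.
2. **Monotone noise filter.** Each simulated curve is projected onto the
   nearest non-decreasing curve by weighted isotonic regression
   (pool-adjacent-violators, weights = embryos per concentration), and
   filtered values below the benchmark response (BMR) are floored to zero.
   A curve whose filtered maximum stays below the BMR is classified as
   baseline noise. Because adverse-outcome incidences can only accumulate
   with dose, only the non-decreasing direction is modelled; there is no
   biphasic handling.
3. **Activity call.** The activity fraction $f$ is the share of non-noise
   curves; $f > 0.5$ calls the plate active.
4. **BMC and confidence interval.** Every non-noise curve yields a BMC:
   the concentration at which the filtered curve first reaches the BMR,
   interpolated linearly in $\log_{10}$ concentration between the
   bracketing tested concentrations (concentrations span three orders of
   magnitude, so interpolation on the raw scale would be meaningless).
   Noise curves contribute the *highest tested concentration* as an
   explicit sentinel. The reported BMC is the median of the `n_boot`
   values; the confidence interval is the (2.5%, 97.5%) quantiles. A 95%
   interval is the default; the level is configurable.

A result whose median crossing sits at the lowest tested concentration is
flagged (`at_lowest_conc`): the substance would need retesting at lower
concentrations for an accurate potency. Inactive results carry the sentinel
BMC *together with* an explicit inactive flag, so no downstream step can
mistake a sentinel for a measured potency; report tables render these cells
as `Inactive (<max conc>)`.

The filter is this package's own well-defined operator with the properties
the screening literature requires of such noise filters (monotonic pattern
detection, a baseline-noise threshold, a noise verdict); it does not claim
numerical equivalence with any particular published implementation.

### Reproducibility

One root seed drives everything. Each (lab, plate, substance, endpoint)
group derives a child seed by hashing its key, so results are bit-identical
across reruns *and* invariant to the order in which plates are analysed.

### Choosing the BMR

The BMR separates baseline noise from effect and is endpoint-specific.
`estimate_bmr()` scans a candidate grid (default 5–50% in steps of 5) and,
for each threshold, pools the variance of the log10 bootstrap BMCs across
all series active at that threshold. The selected BMR is the lowest
candidate whose pooled variance is within a relative tolerance (default
0.05) of the next candidate's — the lowest threshold that already achieves
the potency precision the data's intrinsic variance allows. Thresholds at
which nothing is active cannot stabilize; if no candidate stabilizes the
highest grid value is returned with a warning. The grid and tolerance are
exposed because no single convention exists; the pipeline default when
estimation is not requested is a fixed 10% for all three endpoints.

## Interlaboratory summaries

Substance-level potency per lab is the **median of the plate BMCs**, with
inactive plates contributing their sentinel. A substance is called inactive
at a lab only when a strict majority of its plates are inactive (a 3–3
split among six duplicate plates therefore stays active, which matches how
mixed duplicate sets are reported in practice). Concordance counting
reports how many substances are inactive everywhere, active everywhere,
active anywhere, and (for substances active in at least one lab) which lab
attains the minimum median BMC — inactive cells enter that minimum at their
sentinel, so a substance active at only one lab is trivially lowest there.

Potency ranking is restricted to substances active in every lab; ranks are
ascending in median BMC with average tie-sharing by default (all four
standard tie rules are exposed). Because averaged ranks depend on the tie
rule in ways that published summaries rarely specify, the package treats
rank *sets* (e.g. the five most potent substances) as the reproducible
quantity rather than individual mean/SD values.

Duplicate reproducibility uses Welch's t-test on log10 BMCs between the two
blinded duplicates within each lab, and between labs per duplicate, with
Bonferroni adjustment within each family; inactive plates enter at the
sentinel. The non-parametric Wilcoxon alternative is run only when every
group has at least six values — below that the test cannot reach
significance and is flagged not-run instead. For the positive-control
weekly pools, a one-way ANOVA with Tukey post hoc and a robust
heteroscedastic trimmed-means alternative (Welch-type F on 20%-trimmed
means with winsorized variances, pairwise Yuen contrasts) are provided;
at zero trim the latter reduces exactly to Welch's ANOVA, which the test
suite uses as an independent cross-check. Fold differences in potency are
ratios of geometric means, consistent with all inference being on the log
scale.

## The synthetic study generator

`generate_study()` emulates the structure the analysis assumes, not any
specific chemistry: per substance a hill-shaped affected probability
$p(c) = p_{bg} + (1-p_{bg})\,/\,(1 + (\mathrm{EC}_{50}/c)^h)$ for mortality
and malformation separately; per lab a pure log10 potency shift applied to
every EC50 (a protocol effect such as media renewal) plus lab-specific
background mortality and malformation rates; triplicate plates; at least
seven log-spaced concentrations up to 100 µM; 12 embryos per test
concentration (matching the vehicle-control density of a 96-well layout,
since real designs rarely publish the per-concentration count); 12 vehicle
and 7 positive-control wells per plate. A single latent uniform per embryo
drives both death times through nested thresholds, so the mortality
monotonicity invariant holds by construction rather than by rejection.

Default lab parameters mirror the qualitative structure of a real
three-lab screen: one lab (LabA) is globally more potent (shift −0.5
log10) with the highest background mortality (9%), one lab (LabC) has an
elevated background malformation rate (10%), and LabB is the reference
(2–3% backgrounds). The positive control is about five-fold more potent at
one lab than the others. These are generator defaults for producing
realistic test data, not empirical claims.

`true_pod()` supplies the analytic ground truth: the concentration where
the true affected-probability curve first exceeds
$\mathrm{background} + (\mathrm{BMR}/100)(1-\mathrm{background})$ — in
closed form for the single-hill mortality endpoints, and by exact numerical
inversion for the composite endpoint, whose true curve is a mixture of the
mortality and malformation hills.

What the generator deliberately does **not** emulate: solubility limits,
volatility and degradation kinetics, within-plate spatial effects,
week-scale drift, and scorer disagreement between phenotype classes. A
pipeline that passes the recovery tests is therefore validated for its
statistical machinery, not for robustness to those real-world artifacts.

## Validation design and problem sizes

The test suite validates the engine along two independent routes:

* **Exact enumeration.** On instances with 3 concentrations and up to 3
  embryos each, every binomial bootstrap outcome is enumerable; the
  oracle re-implements the filter rules from first principles (brute-force
  isotonic fit over block partitions) and computes $f$ and the BMC
  distribution exactly. The bootstrap engine at 10,000 draws must agree
  within ±0.02 on $f$.
* **Parameter recovery.** Steep-hill substances (slope 4, 12 embryos per
  concentration, 7 half-log concentrations, 1000 bootstrap curves) must
  recover the analytic POD within ±0.25 log10 units in at least 90% of 50
  seeded replicates; flat series at a 2% background must stay below the
  activity threshold in at least 95%; and a 10×-per-lab injected potency
  shift must reproduce the lab ordering of median BMCs in at least 90% of
  replicates of the full generate → analyze → summarize chain.

These sizes (50 replicates, 1000–10,000 bootstrap draws, single-substance
studies for the ordering check) were chosen as the smallest instances at
which the binomial noise floor makes the checks meaningful.

## Numerical choices and edge cases

* Isotonic regression uses stack-based PAVA in $O(k)$ per curve; weights
  are the per-concentration embryo counts (uniform weights give the same
  fit in the common balanced design).
* Flooring sub-BMR values to zero after monotonization cannot break
  monotonicity (the floored values form a prefix) and makes the filter
  idempotent.
* A filtered curve that reaches the BMR exactly at a tested concentration
  gets that concentration without interpolation.
* Welch's t on two zero-variance groups: identical groups give p = 1,
  separated groups give p = 0 with a warning (the sampling model is
  degenerate either way).
* Well tables round-trip through CSV bit-exactly: concentrations are
  written with 17 significant digits.

## Known limitations

* The noise filter is a stand-in with the stated properties, not a
  re-implementation of any published curve-correction algorithm; numerical
  results can differ from other implementations in ways that do not affect
  the calls or the order of magnitude of potencies.
* BMC values are only interpolations between tested concentrations;
  effects below the lowest or above the highest tested concentration are
  flagged or sentineled, never extrapolated.
* The BMR-estimation elbow rule is one defensible convention among
  several; its grid and tolerance should be reported with any results.
* Substance-level inactivity by majority-of-plates is a discrete rule; at
  even plate counts a tie is active by construction.
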