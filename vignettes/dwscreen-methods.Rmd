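---
title: "Methods: cumulative contaminant-mixture screening for drinking water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative contaminant-mixture screening for drinking water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwscreen)
```

## The screening problem

Point-of-use drinking water in the United States reaches consumers through
three supply chains — private tapwater (mostly private wells), public-supply
tapwater, and bottled water — that differ sharply in regulation and
monitoring.  Broad-scope target analyses routinely detect mixtures of
inorganic and organic contaminants in all three.  `dwscreen` implements a
harmonized screening workflow for such data: it weights each detected
concentration by a health or bioactivity reference concentration, sums the
resulting quotients per sample under a non-interactive concentration-addition
mixture model, and compares the per-sample cumulative metrics between supply
groups with a permutation test.

The package works on long-format detection records (sample x analyte, with
concentrations in µg/L, reporting limits, and explicit non-detect rows)
constrained to a user-supplied core-analyte catalog so that multi-study data
remain intercomparable.  Non-detects are carried, never imputed: they
contribute exactly zero to every cumulative sum but are counted in coverage
reports.

## Hazard-index screening (TQ, ∑TQ)

For each detected analyte $i$ in sample $j$, the toxicity quotient is

$$\mathrm{TQ}_{ij} = \frac{C_{ij}}{B_i},$$

where $B_i$ is the *most protective* (lowest) available human-health
drinking-water benchmark for the analyte, selected from the hierarchy MCLG,
drinking-water health advisories, WHO guideline values, state values, and
USGS screening levels (HBSL/HHBP).  Ties on value break by a fixed type
priority (MCLG first) so resolution is deterministic.  Enforceable MCL/SOQ
values are carried separately for regulatory context via
`individual_exceedance_table()` and participate in resolution only when no
health-based value is lower.

MCLGs are set to "zero" for carcinogens, which would make the quotient
undefined, so harmonized substitution denominators are applied: 0.1 µg/L for
metals (As, Pb, U), disinfection byproducts, and volatile organics — a
routinely achievable analytical reporting limit — and 0.0001 µg/L for PFOS
and PFOA.  The substitutions are configuration (`substitutions` rules keyed
by analyte class with per-analyte overrides), not hard-coded chemistry, so
they are auditable and replaceable.  Two consequences worth internalizing: a
1 µg/L arsenic detection has TQ = 10, and a 0.004 µg/L PFOA detection has
TQ = 40 — substituted denominators deliberately make *any* quantifiable
detection of a no-safe-dose contaminant register as elevated risk.

Per sample, $\sum TQ = \sum_i \mathrm{TQ}_{ij}$ over detections with
$\mathrm{TQ} \ge 10^{-5}$ (the assessment-inclusion floor; quotients below
it are numerically irrelevant and excluded from coverage counts of assessed
chemicals).  Reporting thresholds are 0.1 (a widely used precautionary
screening level) and 1 (benchmark-equivalent cumulative exposure), both
compared with strict `>`; individual exceedance comparisons also use strict
inequality, with an MCLG of zero exceeded by any detection.

## Bioactivity screening (EAR, ∑EAR)

The exposure-activity ratio replaces the apical benchmark with an in vitro
activity concentration at cutoff (ACC) from high-throughput screening:
$\mathrm{EAR}_{ij} = C_{ij} / \mathrm{ACC}_i$.  ACC records flagged as
non-specific-endpoint, baseline, or unreliable response-curve assays are
excluded before any ratio is formed (`filter_endpoints()`).  EAR screening
applies to organic contaminants only; inorganic and microbial records never
enter.

A chemical typically has many assay endpoints.  The chemical-level value
summed across chemicals defaults to the **maximum EAR across retained
endpoints** (`max_endpoint`), the conservative convention for
screening-level prioritization; endpoint-wise summation (`per_endpoint`) is
available as a configuration alternative because the aggregation choice is
genuinely open in screening practice.  The choice in effect is recorded in
the run manifest of every pipeline run.  ∑EAR uses the same inclusion floor
($\ge 10^{-5}$) and is reported against 0.001 — the screening level of
potential concern, calibrated to the TQ = 0.1 convention — and 1.

ACC values are stored in µg/L for direct ratio with concentrations;
µM ↔ µg/L conversion uses the catalog molecular weight
($\mathrm{ACC}_{\mu g/L} = \mathrm{ACC}_{\mu M} \times MW$, since
µmol/L × g/mol = µg/L).

## Toxicokinetically adjusted screening (∑EAR-MED)

The third tier translates the in vitro ACC to an administered-dose scale via
steady-state reverse dosimetry.  The chain:

1. **Measured equivalent dose.**
   $\mathrm{MED} = C\,(\mu g/L) \times 0.2\,\mathrm{L\,kg^{-1}\,d^{-1}}
   \times 0.001\,\mathrm{mg/\mu g}$, using the conservative
   birth-to-one-month water-ingestion rate of 0.2 L per kg body weight per
   day.  (Guideline tables sometimes print this rate in mass units as
   "200 mg kg⁻¹ d⁻¹"; the volumetric 0.2 L/kg/d of the dose equation is what
   is implemented, and only that.)
2. **Steady-state plasma concentration.**  A three-compartment steady-state
   model with restrictive clearance and 100 % oral bioavailability.
   Whole-liver intrinsic clearance (L/h) scales the per-cell rate by
   hepatocellularity and liver mass; hepatic clearance follows the
   well-stirred model $CL_h = Q f_{up} CL_{int} / (Q + f_{up} CL_{int})$;
   renal clearance is glomerular filtration of unbound chemical,
   $CL_r = \mathrm{GFR} \times f_{up}$.  For a dose rate $D$ (mg/kg/d),
   $C_{ss}\,(\mathrm{mg/L}) = D \cdot BW / 24 / (CL_r + CL_h)$, converted to
   µM through the molecular weight.  Useful limits (and test anchors):
   $CL_{int} = 0 \Rightarrow C_{ss} = \dot d/(\mathrm{GFR}\,f_{up})$;
   $CL_{int} \to \infty, f_{up} = 1 \Rightarrow
   C_{ss} = \dot d/(\mathrm{GFR} + Q)$.
3. **Population variability.**  Monte Carlo draws of intrinsic clearance,
   fraction unbound, liver blood flow, and glomerular filtration rate from
   independent truncated normals about their central values (default CV 0.3
   each, positive support, $f_{up} \le 1$); the 95th percentile of the
   resulting Css per unit dose is $C_{ss,95}$.  The distributional form and
   CV are transparent package defaults, exposed in `variability_spec()`,
   because population toxicokinetic variability has no single canonical
   parameterization; with all CVs zero the machinery degenerates exactly to
   the deterministic model.
4. **Reverse dosimetry.**  Per endpoint,
   $\mathrm{AED}_{95} = \mathrm{ACC}\,(\mu M) \times 1\,\mathrm{mg\,kg^{-1}
   d^{-1}} / C_{ss,95}\,(\mu M)$ — the daily dose at which the conservative
   plasma concentration reaches the assay cutoff.  (The subscript follows
   the convention of naming the dose for the Css quantile that drives it,
   although as a dose it is a lower — 5th-percentile-like — population
   estimate.)
5. **Chemical floor and EAR_MED.**  Per chemical, the floor is the 5th
   percentile of its AED$_{95}$ values across endpoints (linear
   interpolation); $\mathrm{EAR}_{MED} = \mathrm{MED} / \mathrm{AED\ floor}$,
   summed per sample with the same inclusion floor and thresholds as ∑EAR.

Chemicals lacking molecular weight, fraction unbound, or intrinsic clearance
are excluded from ∑EAR-MED and surfaced in the coverage attribute — the
same pattern as missing benchmarks or missing ACC data, and, as in real
harmonized datasets, a substantial fraction of detected organics.

Default physiology (70 kg body weight, 90 L/h liver blood flow, 6.7 L/h
GFR, 110×10⁶ hepatocytes/g, 1820 g liver) represents a reference adult and
is fully configurable.  Each chemical's Monte Carlo stream is seeded from a
deterministic hash of the run seed and the analyte id, so results are
independent of table order and reproducible end to end.

## Group comparison (PERMANOVA)

Supply groups are compared on per-sample metrics by one-way PERMANOVA on
Euclidean distances, with
$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = \frac{SS_{among}/(a-1)}{SS_{within}/(N-a)}$.  The permutation
p-value uses add-one smoothing, $p = (1 + b)/(1 + m)$ with $b$ the number
of permuted statistics at least as large as the observed one, so $p > 0$
always and the observed labeling is never re-counted among the $m$ random
permutations.  Small instances can be enumerated exactly
(`exact = TRUE`), which the test suite uses as the oracle for the sampled
version.  Degenerate all-equal data return $p = 1$ (and NaN F) rather than
an error so pipelines on pathological synthetic inputs complete;
perfectly separated groups return $F = +\infty$ with $p$ still from
permutation counts.  Comparisons default to raw metric values; a
`log10(x + 1e-8)` transform is available because cumulative quotients span
orders of magnitude, without any claim that either choice reproduces a
particular published p-value.

## The synthetic-data generator

`generate_dataset()` draws, per sample and analyte, presence as
Bernoulli(detection probability), then a lognormal concentration
left-censored at the analyte's reporting limit — the minimal right-skewed,
censorable model consistent with concentrations spanning orders of
magnitude in broad-scope water data.  Ground truth records the generating
parameters and the analytic probabilities
$P(\mathrm{detect}) = p\,(1 - F(RL))$ and
$P(\mathrm{TQ} > 1) = p\,(1 - F(\max(B, RL)))$, so pipeline recovery is
checkable in closed form.  Reporting limits are fixed per analyte by
default, with an optional per-study column because multi-study data carry
study-specific limits.

`three_supply_scenario()` packages a three-supply scenario at the harmonized
study sizes (98 private-tapwater, 126 public-tapwater, 30 bottled-water
samples; 254 total) whose *qualitative* structure mirrors the observed
supply contrasts — geogenic metals (As, Pb, U, Mn) enriched in private
tapwater and groundwater-sourced bottled water, disinfection byproducts
concentrated in chlorinated public supply and purified-tapwater-style
bottled samples, a PFAS class present in tapwater only, pesticides mostly
rural/private — while every numeric rate (detection probabilities,
lognormal parameters, benchmark, ACC and TK values) is synthetic.  It also
builds in the coverage gaps real harmonized data have: analytes without
benchmarks, organics without ACC endpoints or TK parameters, flagged
assay endpoints, one non-core analyte, and a pass-through microbial
indicator that is never screened.

What passing tests on this generator do and do not show: they verify the
arithmetic, censoring, coverage accounting, and group-comparison machinery
against known ground truth; they do not validate the lognormal/Bernoulli
model against real exposure data, spatial or temporal correlation, between-
analyte co-occurrence, or laboratory artifacts — none of which the generator
emulates.

## Numerical conventions

* Quantiles everywhere (group summaries, Css 95th percentile, AED 5th
  percentile) use linear interpolation between order statistics (R type 7);
  quantile conventions change results, so the choice is stated in the run
  manifest.
* Threshold comparisons: strict `>` at 1, 0.1 and 0.001; inclusion floors
  use `>=` at $10^{-5}$.
* CSV output renders doubles at 17 significant digits, so write/read
  round-trips are lossless and reruns with the same seed are byte-identical.
* Scales: concentrations µg/L (ng/L converted on ingest; microbial counts
  CFU/100 mL carried but never screened); doses mg/kg/d; ACC and Css µM
  where dose conversion is involved.

## Problem sizes

The packaged scenario runs the full pipeline (254 samples, 21 analytes,
9999-permutation PERMANOVA per metric, 1000-draw Monte Carlo per chemical)
in a few seconds.  The test suite exercises parameter recovery at 2000
samples and permutation-vs-exact agreement at $N = 8$, sizes at which the
binomial and enumeration oracles are sharp.

## Known limitations

* Concentration addition is assumed exactly; no interaction (synergism or
  potentiation) model is provided.
* The steady-state model is three-compartment with restrictive clearance
  and complete oral bioavailability; no absorption, gut, or multi-tissue
  partitioning model, and a single ingestion-rate constant rather than
  age-resolved physiology.
* EAR aggregation across endpoints is a screening convention, not an
  effect model; neither aggregation mode should be read as a health-risk
  estimate.
* Benchmarks, ACC values, and TK parameters are inputs; the package derives
  none of them from toxicology.
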