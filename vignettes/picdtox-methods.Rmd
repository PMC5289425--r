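---
title: "Methods: PBPK-based contextualization of in vitro hepatotoxicity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBPK-based contextualization of in vitro hepatotoxicity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling choices behind `picdtox`: the PBPK
engine, the in vitro → in vivo contextualization (PICD), the toxic-change
analytics, and the synthetic-data generator that stands in for real
hepatocyte transcriptomics. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The whole-body PBPK engine

### Structure and assumptions

The body is a set of well-stirred organ compartments connected by blood
flow. The shipped physiologies (73 kg human, 250 g rat) contain 15
compartments: 13 perfused organs plus venous and arterial blood pools.
Circulation is fixed: venous pool → lung → arterial pool → tissues →
venous pool, with the splanchnic organs (gut, spleen, pancreas, stomach)
draining through the portal vein into the liver. Blood is treated as a
homogeneous pool for transport (no red-cell partitioning of mass flow);
the sub-compartment concentrations reported for an organ are derived
algebraically from the organ state:

* plasma and interstitial concentration: organ concentration divided by
  the partition coefficient (endothelial exchange is unlimited by
  default);
* intracellular concentration: the remainder after assigning the
  vascular and interstitial spaces, clamped at zero for reporting.

When a per-organ endothelial permeability override is set (the mechanism
for drugs so strongly protein-bound that capillary escape limits tissue
uptake), the organ splits into a vascular and an extravascular state
exchanging with permeability × surface area kinetics; the capillary
surface area is a fixture constant of 7000 cm² per litre of organ
volume.

### Partition coefficients

The default (`method = "composition"`) is deliberately simple and fully
documented:

\[
K_p = f_u \cdot \frac{f_{\text{water}} + P \cdot f_{\text{lipid}}}
       {f_{\text{water},p} + P \cdot f_{\text{lipid},p}}, \qquad
P = 10^{\log P}.
\]

It is registered behind a method registry
(`register_partition_method()`) so alternative calculations can be
added. The commercial distribution calculations used in whole-body PBPK
platforms are intentionally not reproduced; the analysis needs a
self-consistent engine, not bit-compatibility with any one vendor
algorithm. Consequences worth knowing: $K_p$ is proportional to $f_u$,
monotone in log P with organ lipid content, equal to 1 in the
water-only/neutral limit, and independent of organ volumes.

### Processes, clearances, dosing

Saturable metabolism and transport are Michaelis–Menten with `vmax`
referenced to intracellular volume and scaled by a per-organ relative
expression factor; the driving concentration is the organ plasma
concentration (well-stirred convention), which keeps low-$f_u$ compounds
from stalling their own metabolism through the intracellular remainder.
Metabolites are first-class compounds: conversion is mole-for-mole and
the products circulate in the same physiology. Renal clearance samples
the kidney plasma concentration and routes to urine (an absolute
ml/h/kg mode and a GFR-fraction mode acting on unbound drug); biliary
clearance samples liver plasma and routes to bile, treated as terminal
elimination (no enterohepatic recirculation — the data to parameterize
recirculation are not part of this workflow); hepatic plasma clearance
is an unspecific first-pass term tracked as cleared mass so the balance
closes. Oral dosing fills a gut lumen from which a first-order rate
`ka = permeability × surface / volume` (fixture constants 7000 cm²,
1 L) absorbs the dissolved fraction; solubility caps the dissolved
amount. Doses in mg convert to µmol at intake; everything internal is
h / µmol / µmol/L.

### Numerics

`deSolve::lsoda` with rtol 1e-8 / atol 1e-10, at least 200 output
points per 24 h, and — important for exposure integrals — a log-spaced
output refinement after every dose event. An IV bolus mixes out of the
venous pool with a time constant of minutes; on a uniform grid the
trapezoidal AUC of that transient is biased upward by several per cent,
which is exactly the quantity PICD matches. With the refinement the
trapezoidal liver AUC agrees with an independently integrated quadrature
state to ~2·10⁻⁴ relative at default settings. Doses administered at
t = 0 seed the initial state; later doses are solver events, and the
mass-balance bookkeeping counts an event dose strictly after its dose
time because the solver reports the state at an event time before
applying the event. Mass balance (dose = body + urine + bile + cleared,
summed over parent and metabolites) is checked to 0.01 % in every suite
simulation.

### Parameter fitting

`fit_pbpk()` estimates parameters addressed by label
(`clearance.<compound>.<kind>`, `process.<enzyme>.<vmax|Km>`) by
Levenberg–Marquardt least squares. Two numerical choices matter:

* `log_residuals = TRUE` fits on the log-concentration scale — the
  proportional-error model appropriate for multiplicative assay noise.
  Under absolute-scale fitting, the informative low-concentration tail
  carries almost no weight and saturable-elimination parameters inherit
  a large dispersion.
* the finite-difference Jacobian steps are scaled to the ODE solver's
  noise floor (`epsfcn = rtol`); with machine-epsilon steps the
  derivative estimates drown in integration noise and the optimizer
  stalls far from the optimum.

A locally flat objective direction (non-identifiable parameter) is
detected by perturbation and reported as a warning. A joint fit of a
linear clearance and a saturable `vmax` from a single venous profile is
close to a trade-off ridge; the recovery studies in the test suite
therefore estimate each parameter in a well-posed design (clearance in a
linear setting; `vmax` with clearance known), which is what a
pharmacometrician would do.

## PICD: AUC matching and contextualization

The matching rule equates the in vitro exposure AUC (concentration ×
duration under the constant-medium assumption) with the simulated total
liver-interstitial AUC over the same window, starting at the first dose.
Total rather than unbound concentration is the default; `unbound = TRUE`
switches the convention. The dose search probes linearity with two
simulations and scales directly when AUC doubles with dose (verified
against the tolerance afterwards); otherwise a bracketed bisection runs
to a relative AUC mismatch below 1e-6 with deterministic iteration caps
and automatic bracket expansion.

Dose–response maps interpolate linearly on the natural dose scale
(log-dose is available) between the per-level anchor doses, always
including the implicit (0, 0) anchor. Doses above the highest anchor are
clamped to the highest anchor's response with a warning: extrapolating
transcriptomic response beyond measured exposure has no support in the
data, and saturation is the defensible behavior. When 2 h responses are
not measured, the 2 h value is interpolated linearly in time between
(0 h, 0) and the 8 h value — zero response at dose start is the only
defensible intercept; the interpolation anchor is a documented choice,
not a data-derived fact.

## Toxic-change analytics

Gene response is |log2FC|; process and functional-class responses are
arithmetic means over member genes present in the data (absent members
are excluded and counted in a coverage report, not imputed as zero,
which would bias process means downward silently). The toxic change of
an entity is the toxic-dose response minus the therapeutic-dose
response, preserved with sign; a count of negative values is attached
rather than clamped.

Over-representation uses the one-sided hypergeometric tail with
Benjamini–Hochberg correction per drug across processes (drugs are
separate experiments; pooling across drugs would couple their error
rates). The responder criterion feeding it — |log2FC| ≥ 1 at any
concentration of a timepoint — is a documented, configurable default;
the upstream assay convention it stands for is not recoverable from the
workflow itself. Key processes require adjusted p < 0.01 in at least a
third of the drugs, irrespective of timepoint; perturbed processes
require a group-mean toxic change of at least 0.10 at a timepoint, with
an exclusivity report against the complementary group.

Clustering is Ward's minimum variance (`ward.D2` on unsquared Euclidean
distances) on row-normalized (mean 0, sample SD 1) toxic-change
matrices; drugs are clustered on their concatenated timepoint profiles
and the two-group cut is labelled high/low by the unnormalized column
means. Group comparisons are pooled-variance two-sample t-tests (Welch
by flag) with the confidence interval oriented first-named minus
second-named group; Pearson confidence intervals use the Fisher
z-transform.

Biomarker rules are evaluated per (process, timepoint) scope over the
high-responsive group: the unsubscripted grand mean and SD are taken
over all (gene, drug) toxic changes of that scope, a reading consistent
with per-timepoint reporting of biomarkers; a global-scope variant is a
parameter away. Inequalities are strict. Common biomarkers need a group
mean above 1.5× the grand mean and an across-drug SD below 0.5× the
grand SD; individual biomarkers need a single drug's toxic change above
7× the grand mean. Threshold robustness is reported by a ±5 % sweep of
all three multipliers. DDI prediction declares every unordered pair
sharing at least one individual-biomarker gene; shared genes are ranked
by ascending absolute toxic-change difference (most similar toxic
action first — shared mechanism is the interaction hypothesis), and
confusion metrics leave zero-denominator ratios as missing rather than
coercing them.

Differential response pathways compare two drugs gene-by-gene
(threshold 0.15 on the toxic-change difference, and 0.15 for
"similar-high" on both drugs — the thresholds live on the same
absolute-log2FC scale as toxic change itself) and induce the subgraph on
flagged genes exactly: no one-hop connector inclusion, because induced
semantics is the only reproducible choice.

## The synthetic study

The generator emulates the shape of primary-hepatocyte response
tensors: 15 drugs (8 high-responsive, 7 low-responsive), 74 gene sets
of 15–30 genes over a 2500-gene universe, 3 assay concentrations
(1, 5, 25 µM with response multipliers 0.25/0.5/1.0) and timepoints
2/8/24 h (multipliers 0.3/0.7/1.0 — monotone dose and time response).
Signed log2FC = planted effect × concentration factor × time factor +
N(0, 0.1); responses are absolute values, which makes the zero-effect
baseline the analytic folded-normal mean σ√(2/π).

Planted structure, all recorded in a ground-truth manifest:

* ten affected processes carry per-(gene, drug) effects of amplitude
  1.2 × U(0.3, 1.7) in the high group and 0.02 × U(0.3, 1.7) in the low
  group — large enough that responder genes exist at the high
  concentration, small enough that low-group process means stay well
  under the 0.10 perturbation threshold;
* two common biomarkers per affected process at constant amplitude
  across the high drugs, and per-pair spike genes (plus a few private
  ones) for single drugs. Spike and common amplitudes are set
  *self-consistently* within each (process, timepoint) scope: with `n`
  values of which `n_c` are common (at `c×` the scope mean) and `n_s`
  spiked (at `s×`), the realized mean is
  `m = Σ(background) / (n − c·n_c − s·n_s)`, so planted commons sit at
  exactly 3× and spikes at exactly 15× the scope mean they themselves
  shift. Without the joint solve, sequentially planted amplitudes drift
  below their nominal multiples as each addition inflates the scope
  mean. Spike genes are assigned greedily to the scope with the largest
  remaining capacity so every denominator stays comfortably positive;
* seventeen of the 28 high-group pairs share a spiked gene (the spiked
  genes carry the cytochrome-P450 functional class), and the reference
  interaction list is constructed so the evaluation realizes the target
  confusion counts (TP 12, FP 5, TN 7, FN 4) exactly — the worked
  arithmetic the DDI metrics are checked against.

The study's therapeutic and toxic doses are the PICD-identified doses of
the lowest and highest assay concentration, which makes contextualized
responses round-trip the assay responses exactly and keeps the planted
structure analyzable end-to-end. Recovery assertions are evaluated at
24 h, where the signal-to-noise ratio is highest.

What passing recovery tests do **not** show about real data: the
generator has no probe-level noise, batch effects, replicate structure,
correlated genes, or overlap between gene sets, its noise is Gaussian
and homoscedastic, and its dose–response is exactly linear between
anchors. The pipeline's statistical operations are validated against
independent oracles; its biological conclusions on real tensors depend
on assumptions the generator does not test.

## Problem sizes and determinism

The default synthetic study (15 drugs × 2500 genes × 3 concentrations ×
3 timepoints, ~130 PBPK simulations for the dose maps) runs in well
under a minute; recovery studies use 10–20 noise seeds; the dose-search
oracle scans 10,000 doses of an independently integrated reduced system.
All randomness forks from a single root seed per stage, so a pipeline
rerun with the same configuration is byte-identical, which the suite
asserts on the exported CSVs.

## Known limitations

* The PBPK engine is a minimal perfusion-limited model: no
  permeability-limited tissues except via the endothelial override, no
  dissolution kinetics beyond the solubility cap, no population
  variability, no plasma-protein binding kinetics.
* PICD's constant-medium assumption ignores in vitro depletion and
  binding in the assay medium.
* The composition-based partition method is one documented choice among
  several used in practice; absolute tissue exposures shift with the
  method, though the AUC-matching construction makes downstream toxic
  changes depend only weakly on it (anchors move together).
* Biomarker scope statistics assume enough genes per scope; scopes with
  fewer than two genes are skipped with a warning.
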