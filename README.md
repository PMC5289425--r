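# picdtox

Comparative analysis of drug-induced hepatotoxicity in a patient context:
a minimal whole-body PBPK simulator coupled to PBPK-based in vivo
contextualization of in vitro toxicity data (PICD), toxic-change
analytics, molecular-biomarker identification and drug–drug interaction
(DDI) prediction.

## Who this is for

Computational toxicologists and pharmacometricians who want to transfer
in vitro hepatocyte transcriptomics (log2 fold changes measured at a few
assay concentrations and timepoints) into an in vivo dosing context, and
then compare drugs by the *toxic change* their dose escalation induces.
Everything runs on seeded synthetic data with the statistical structure
of primary-hepatocyte response tensors, so the full pipeline is testable
without any external downloads.

## The model in brief

**PBPK core.** Organs are well-stirred compartments connected by blood
flow (venous pool → lung → arterial pool → tissues; splanchnic organs
drain through the portal vein into the liver). Tissue partition
coefficients come from a documented composition calculation,

    Kp(organ) = fu · (f_water + P · f_lipid) / (f_water,p + P · f_lipid,p),   P = 10^logP,

saturable metabolism and transport follow Michaelis–Menten kinetics
(`vmax`, `Km`) referenced to intracellular volume, and renal/biliary/
hepatic plasma clearances are linear and body-weight scaled. Internal
units: h, µmol, µmol/L; mass balance is conserved to < 0.01 %.

**PICD.** For an in vitro exposure at concentration `C` over duration
`T` (AUC_vitro = C·T), the matching in vivo dose `d*` solves

    AUC_liver,interstitial(d*, [0, T]) = AUC_vitro,

found by dose-linearity probing plus bracketed bisection (relative AUC
tolerance 1e-6). Each assay concentration becomes a dose anchor; gene
responses (|log2FC|) interpolate linearly between anchors, giving
time-resolved in vivo response predictions for any dose.

**Toxic change.** For entity `x` (gene, process, or functional class
within a process), drug `d` and timepoint `t`:

    toxic_change(t, x, d) = response_toxic(t, x, d) − response_therapeutic(t, x, d).

**Downstream analytics.** Over-representation of toxicity gene sets
(one-sided hypergeometric, Benjamini–Hochberg within drug, adjusted
p < 0.01 in ≥ 1/3 of drugs), Ward (`ward.D2`) clustering of row-normalized
toxic-change profiles into high/low-responsive drug groups,
perturbed-process selection (mean toxic change ≥ 0.10), biomarker rules

    common:     mean_g > 1.5 · mean  AND  sd_g < 0.5 · sd      (per process × timepoint scope)
    individual: tc(d, g) > 7 · mean,

DDI prediction (a pair is predicted when both drugs share an individual
biomarker gene; shared genes ranked by ascending |Δ toxic change|), and
confusion-matrix evaluation (accuracy, sensitivity, specificity,
precision) against a reference pair list.

## Worked example

```r
library(picdtox)

## a one-compartment sanity check: V = 10 L, CL = 1 L/h, 10 mg IV bolus
m   <- one_compartment_model(volume_l = 10, clearance_l_h = 1,
                             molecular_weight = 100)
sim <- simulate_pk(m, dosing_regimen("iv_bolus", dose = 10), t_end = 24)
get_profile(sim)
#> <pk_profile drug @ venous_plasma: 301 points, t 0-24 h, Cmax 10>
compute_auc(get_profile(sim), c(0, 24)) * 100 / 1000   # µmol/L -> mg/L
#> [1] 9.09291
```

`Cmax = 10 µmol/L` is the bolus concentration 10 mg / (10 L × 100 g/mol)
and the 0–24 h AUC matches the closed form 10·(1 − e^(−2.4)) = 9.093
mg·h/L.

```r
## the full synthetic comparative study (15 drugs, 74 gene sets)
study <- run_pipeline(seed = 1)
study
#> <picd_study>
#>   drugs: 15 (8 high-responsive: AD, APAP, AZA, CPA, CSA, DFN, ERY, FT)
#>   key processes: 10; common biomarkers: 20; individual biomarker entries: 114
#> <ddi_evaluation: TP 12, FP 5, TN 7, FN 4 (of 28 pairs)>
#>   accuracy 67.9%  sensitivity 75.0%  specificity 58.3%  precision 70.6%
```

The printed DDI block is the evaluation of predicted drug pairs against
the study's reference interactions over all 28 unordered pairs of the 8
high-responsive drugs; the four percentages are the confusion-matrix
summaries defined above. `study$manifest` carries the generator's planted
ground truth so every recovery claim can be audited.

A thin CLI for the main verbs ships in `inst/cli/picdtox.R`
(`synth`, `simulate-pk`, `run`).

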