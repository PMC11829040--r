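---
title: "Modeling aniline-free hydrazine chemistry for RNA-modification mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling aniline-free hydrazine chemistry for RNA-modification mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydramass)
```

## The problem

Pseudouridine (Ψ) is an isomer of uridine: identical elemental composition
(C9H12N2O6, monoisotopic 244.0695 Da), identical base pairing, and therefore
invisible to both sequencing and direct mass spectrometry. What separates
the two is chemistry. Hydrazine attacks the electrophilic C6 of uridine,
cyclizes across C4–C6 and expels a pyrazolone molecule, leaving a
urea–ribose moiety on the strand that is 52 Da lighter (net composition
change −C3O, monoisotopic −51.9949 Da). The C-glycosidic Ψ lacks the
required electrophilicity and survives. Run aniline-free and cold, the
reaction leaves the phosphodiester backbone intact, so the mass loss can be
read out directly from intact oligonucleotides: an RNase T1 fragment with
*r* convertible uridines shows a ladder of peaks spaced 52 Da apart, and a
ladder that stops early betrays Ψ.

`hydramass` implements this reasoning as a reusable analysis toolchain:

1. **chem_core** — elemental-composition algebra, monoisotopic / average /
   nominal masses, positive-mode m/z with mixed cation adducts, ppm errors;
2. **registry** — nucleoside formulas, hydrazine reaction rules and
   dose–response reactivities, as a versioned YAML data file;
3. **digestion** — bracket-notation sequences and in-silico RNase T1
   digestion with exact terminus bookkeeping;
4. **ladder / matching** — conversion-ladder enumeration, theoretical peak
   prediction, tolerance matching, Ψ-candidate counting, neutral-loss
   annotation;
5. **quantification** — calibration curves, guanosine normalization,
   conversion yields, log-logistic dose–response fits;
6. **simulators** — seeded generators for every input the pipeline reads.

## Mass conventions

Masses are linear in element counts over a deliberately small table (C, H,
N, O, P, S, plus F for the flunarizine calibrant), tabulated to six
decimals. Positive-mode m/z uses the common simplification

$$ m/z = \frac{M + \sum_i m_{\text{cation},i}}{z} $$

with the proton at 1.007276 Da and Na⁺/K⁺/NH₄⁺ each replacing one proton;
the electron mass is absorbed into the cation constants. This convention
reproduces the instrument-printed lockmass values ([M+H]⁺ of carbamazepine
237.10224, flunarizine 405.21368, reserpine 609.28066) to all five printed
decimals, which is the precision regime the package targets.

```{r lockmass}
mz_from_mass(mono_mass("C15H12N2O"), ion_descriptor(1))  # carbamazepine
```

## Terminus bookkeeping

Oligonucleotide masses are where sign errors of ±18 (water) and ±80 (HPO3)
classically creep in. The package fixes one formula: a residue is a
nucleoside 5′-monophosphate minus water; an oligo is the residue sum plus
one water (giving a 5′-phosphate/3′-OH chain); a 5′-OH subtracts HPO3, a
3′-phosphate adds it, and a 2′,3′-cyclic phosphate additionally subtracts
water. Consequences that the tests pin down: a single 5′-OH/3′-OH residue
is exactly the free nucleoside; an RNase T1 product (5′-OH/3′-phosphate)
weighs the same as the 5′-phosphate/3′-OH form; each T1 cut adds one water
across the products; cyclic and linear products differ by exactly 18.0106.

RNase T1 is modeled as cleaving 3′ of unmodified G only. 2′-O-methylation
(Gm) blocks the 2′-OH-dependent transesterification chemistry, and
base-methylated guanosines (m1G, m2G, m22G, m7G) are kept in the default
resistant set; the set is a function argument, not a constant. The default
product terminus is the linear 3′-phosphate — a 30-minute digestion
ring-opens the cyclic intermediate — but both variants are offered to the
peak matcher, because annotated spectra rarely say which form they assume.

## The reaction registry

Reaction rules live in `inst/extdata/registry.yaml`, not in code, so users
can refit or extend them (`load_registry()`, `register_nucleoside()`). Each
rule carries a signed composition delta and a mechanism tag:

| reactant | product | net change | mono Δ (Da) |
|---|---|---|---|
| U, acp3U, Um | urea–ribose | −C3O | −51.995 |
| m3C, s2C | aminopyrazole loss | −C3HN | −51.011 |
| ac4C | cytidine (deacetylation) | −C2H2O | −42.011 |
| s4U | C4 hydrazone, S eliminated | +N2H2−S | −1.950 |
| D | ring-opened C4 hydrazide | +N2H4 | +32.037 |
| m7G | N7-methyl-FAPy-G (hydroxide) | +H2O | +18.011 |
| mcm5s2U | unknown | — | — |

Two rules deserve comment. The dihydrouridine product could retain the
hydrolysis water (+N2H4+H2O) or not (+N2H4) depending on whether ring
opening precedes hydrazide formation; the registry defaults to +N2H4 and
the alternative is a one-line re-registration. t6A reactivity differs
between E. coli and human tRNA preparations although the nucleoside is
chemically identical in both — the difference is attributed to a cofactor
in the preparation, so it is encoded as a registry *profile* switch
(`default_registry("ecoli")`), not as chemistry. Rules with unknown product
mass (mcm5s2U, E. coli t6A) still contribute to loss-based quantification
but are flagged and excluded from ladder mass prediction.

## The reactivity model

Observed conversion is summarized by a two-parameter log-logistic in
hydrazine concentration (% v/v),

$$ p(c) = \frac{p_{\max}}{1 + (\mathrm{EC}_{50}/c)^{h}}, \qquad p(0)=0, $$

referenced to 0 °C / 1 h. The experiments behind it give an ordering and a
handful of anchor points rather than a functional form, so the registry
parameters are calibrated once against those anchors: s4U, m3C and
mcm5s2U nearly fully lost at 10% while U is ~5% converted; ac4C and D gone
at 30%; m7G down to ~25% remaining and acp3U ~40% converted at 30%; s2C
inert at 30%; U half-converted at 50%. Um converts with its ceiling reduced
to 0.5 (partial reactivity of the 2′-O-methylated ribose). Time enters as
a multiplicative factor linear in hours and capped at 6 h — the available
time-course data are too sparse for kinetics — and temperature is a flagged
extrapolation rather than an Arrhenius term, because above ~10 °C the
dominant effect is strand degradation, not faster conversion
(`degradation_flag()` encodes the observed stability map, and the
simulators refuse quantitative runs under degrading conditions).

```{r reactivity}
vapply(c(0, 10, 30, 50), function(c)
  reactivity("U", treatment_condition(c)), numeric(1))
```

## Ladders, matching and what a ladder can and cannot say

`conversion_ladder()` enumerates all subsets of reactive positions and
collapses states with identical total delta — identical-mass species are
indistinguishable, so the collapsed state keeps the smallest conversion
count as its label. With a treatment condition attached, species get exact
Bernoulli-product probabilities (verified against 2^r brute-force
enumeration for r ≤ 10). Matching assigns each observed peak to the nearest
theoretical peak within tolerance (10 ppm HRMS / 0.5 Da MALDI defaults,
mirroring common precursor settings), breaking ties by |ppm|, then lower k,
then lower z, and flagging exact ties as ambiguous.

Ψ inference is deliberately modest: with *u* U-or-Ψ positions and maximum
assigned conversion count *k*max, the fragment contains *u − k*max
non-reactive sites. An MS1 ladder counts sites; it cannot localize them
unless all or none are implicated, and the package never pretends
otherwise (localization needs MS² coverage, which is out of scope). When
the per-site conversion probability under the stated condition is below
0.9, unconverted U cannot be excluded and the call is flagged
low-confidence.

```{r ladder}
ont <- tokenize("A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG")  # tRNA-Phe anticodon ONT
conversion_ladder(ont)[, c("k", "delta_nominal", "mass_mono")]
```

## Quantification

Calibration follows the instrument design: a 12-point 1:1 serial dilution
(canonicals from 100 pmol, Ψ and D from 20 pmol, other modifications from
5 pmol), fitted by unweighted OLS with intercept (1/x weighting available
— the experimental write-ups do not state a weighting, so the simplest
choice is the default). Amounts become per-molecule counts by normalizing
to guanosine, which hydrazine leaves untouched; conversion yield is
1 − treated/control, clipped to [0, 1] with the raw value retained for
diagnostics.

Dose–response curves are fitted on the remaining-fraction scale by bounded
Levenberg–Marquardt (`minpack.lm`), ceiling constrained to [0, 1]. One
numerical caveat is documented rather than hidden: when the 0–50% hydrazine
window does not reach a species' plateau, the free three-parameter fit is
weakly identified — ceiling and EC50 trade off along a ridge. For that
regime `fit_dose_response(..., fix_ceiling = 1)` restores identifiability
and is what the cross-species EC50 ranking uses (all ranked species are
known full converters). Flat series return a near-zero ceiling with an
`ec50_unidentifiable` flag; near-step series are flagged `steep`.

## What the simulators emulate — and what they do not

`simulate_treatment()` draws per-molecule, per-site Bernoulli conversions
(so conversion counts are exactly Binomial when sites share one
probability); `simulate_peaklist()` places peaks at theoretical m/z with
Gaussian jitter (ppm for ESI, Da for MALDI), log-normal multiplicative
intensity noise and Poisson-count spurious peaks; the calibration and
concentration-series simulators add multiplicative Gaussian noise to exact
designs. Every simulator takes an explicit seed and restores the caller's
RNG state.

Not emulated: chromatography and ion suppression, isotope envelopes,
sequence-dependent reactivity (the structure-accessibility effects seen in
folded tRNA), partial digestion kinetics, and real instrument baselines.
Passing tests therefore demonstrate correctness of the bookkeeping and the
statistical machinery under the model's own assumptions — they say nothing
about, for example, whether a particular stem-buried U converts as readily
as a loop U in a real spectrum.

## Problem sizes and numerical choices

The shipped tests run the heavy properties at sizes chosen to make the
statistics sound while staying quick on a laptop: 1000 random sequences for
digest tiling/mass conservation, 10⁴ molecules for the binomial
goodness-of-fit (χ² at α = 0.01 with sparse tails pooled), 20 seeded
single-replicate simulations for EC50 recovery (median error < 20%), 10⁴
jittered peaks for the 5-ppm/10-ppm normal-tail check, and 100 seeded
end-to-end simulate→match→infer runs (each species observed at two charge
states, as MALDI spectra show singly and doubly protonated ions). Mass
comparisons use 1e-6 Da for arithmetic identities and the instrument's own
printed precision (0.02 m/z, 2 Da MALDI) for worked examples. Species
collapsing rounds deltas to 1e-6 Da; matching tie-breaks are deterministic
so reports are permutation-stable.
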