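# hydramass

Hydrazine reactivity mass spectrometry for RNA modifications.

## The problem

Pseudouridine (Ψ) and uridine (U) are isomers — same formula C9H12N2O6,
same mass — so neither sequencing nor direct MS can tell them apart. Their
chemistry differs: hydrazine attacks C6 of uridine and cleaves off a
pyrazolone, leaving a urea–ribose moiety **52 Da lighter** (net −C3O,
monoisotopic −51.9949 Da), while Ψ is inert. Run aniline-free and cold, the
reaction leaves the RNA backbone intact, so the mass loss is readable from
intact RNase T1 fragments: a fragment with *r* convertible uridines shows a
ladder of peaks spaced 52 Da apart, and a ladder that stops early reveals
pseudouridylated sites. Several modified nucleosides (s4U, m3C, mcm5s2U,
ac4C, D, m7G, acp3U) react at even lower hydrazine concentrations, each
with its own characteristic product mass.

`hydramass` is an R toolchain for scientists analyzing such experiments:

- **exact-mass algebra** on elemental compositions; monoisotopic, average
  and nominal masses; positive-mode m/z with proton/Na/K/NH4 adducts and
  ppm errors;
- a **nucleoside registry** (versioned YAML) of canonical and modified
  ribonucleosides with hydrazine reaction rules and log-logistic
  dose–response reactivities, p(c) = ceiling / (1 + (EC50/c)^h);
- **bracket-notation sequences** (`"A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG"`) with
  in-silico **RNase T1 digestion** and exact terminus bookkeeping;
- **conversion ladders**, theoretical peak prediction, peak matching and
  Ψ-candidate inference (u − kmax sites non-reactive);
- **absolute quantification**: serial-dilution calibration curves,
  guanosine normalization to per-molecule counts, conversion yields
  (1 − treated/control) and dose–response fitting;
- seeded **simulators** for treated molecule populations, noisy peak
  lists, calibration and concentration series.

## Worked example

Match the +4 charge-state ladder of a treated 20-mer and count
non-reactive sites:

```r
library(hydramass)

mer20 <- tokenize("GUAGUCGUGGCCGAGUGGUU")
lad <- conversion_ladder(mer20, condition = treatment_condition(30))
tp  <- theoretical_peaks(lad, charges = 4)

obs <- data.frame(mz = c(1614.23, 1601.22, 1588.22),
                  intensity = c(100, 60, 20))
res <- match_peaks(obs, tp, tolerance = 20)
res$assignments[, c("mz", "theoretical_mz", "k", "z", "ppm")]
#>        mz theoretical_mz k z        ppm
#> 1 1614.23       1614.220 0 4  6.0383643
#> 2 1601.22       1601.222 1 4 -0.9517734
#> 3 1588.22       1588.223 2 4 -1.7599861
```

The three observed peaks are the unreacted oligo and the one- and
two-conversion states, each 51.995/4 ≈ 13.00 m/z apart at +4, all within
the 20 ppm tolerance. Counting sites:

```r
infer_nonreactive_sites(res, mer20)$n_nonreactive
#> [1] 4
```

Six U positions, conversions observed up to k = 2, hence 4 sites did not
react under this (sub-saturating, 30% hydrazine) condition — at saturating
conversion the same count would flag Ψ candidates. The ladder of the
tRNA-Phe anticodon fragment (two Us, one Ψ) stops at −104 Da:

```r
conversion_ladder(tokenize("A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG"))[, 1:2]
#>   k delta_nominal
#> 1 0             0
#> 2 1           -52
#> 3 2          -104
```

And the quantification bookkeeping: an RNA with 16 uridines per molecule
that retains 12 after treatment has

```r
conversion_yield(16, 12)
#> [1] 0.25
```

i.e. a 25% conversion yield.

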