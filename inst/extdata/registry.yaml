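# Ribonucleoside registry: formulas, hydrazine reaction rules and
# dose-response reactivity defaults.
#
# Dose-response parameters refer to the reference condition (0 degC, 1 h)
# and a 2-parameter log-logistic in hydrazine % v/v:
#   p(c) = ceiling / (1 + (ec50 / c)^slope),  p(0) = 0.
# They encode the observed anchor points (at 0 degC / 1 h): s4U, m3C and
# mcm5s2U nearly fully lost at 10% while U is ~5% converted; ac4C and D fully
# lost at 30%; m7G reduced to ~25% remaining at 30%; acp3U ~40% converted at
# 30%; s2C inert at 30%; U ~50% converted at 50%.
version: "1.0"
reference_condition:
  temperature_c: 0
  time_h: 1
nucleosides:
  - code: A
    name: adenosine
    formula: C10H13N5O4
  - code: C
    name: cytidine
    formula: C9H13N3O5
  - code: G
    name: guanosine
    formula: C10H13N5O5
  - code: U
    name: uridine
    formula: C9H12N2O6
    rules:
      - product: urea-ribose
        mechanism: C6-pyrazolone-loss
        leaving_group: pyrazolone
        delta: {"C": -3, "O": -1}
        dose_response: {ec50: 50.0, slope: 1.83, ceiling: 1.0}
  - code: Psi
    name: pseudouridine
    formula: C9H12N2O6
  - code: m5C
    name: 5-methylcytidine
    formula: C10H15N3O5
  - code: m3C
    name: 3-methylcytidine
    formula: C10H15N3O5
    rules:
      - product: urea-ribose (N-methyl)
        mechanism: C6-aminopyrazole-loss
        leaving_group: 3-aminopyrazole
        delta: {"C": -3, "H": -1, "N": -1}
        dose_response: {ec50: 3.0, slope: 3.0, ceiling: 1.0}
  - code: m7G
    name: 7-methylguanosine
    formula: C11H15N5O5
    rules:
      - product: N7-methyl-FAPy-G
        mechanism: hydroxide-FAPy
        delta: {"H": 2, "O": 1}
        dose_response: {ec50: 17.3, slope: 2.0, ceiling: 1.0}
  - code: s4U
    name: 4-thiouridine
    formula: C9H12N2O5S
    rules:
      - product: 4-hydrazone-uridine
        mechanism: C4-hydrazide-S-elimination
        leaving_group: H2S
        delta: {"N": 2, "H": 2, "S": -1}
        dose_response: {ec50: 3.0, slope: 3.0, ceiling: 1.0}
  - code: s2C
    name: 2-thiocytidine
    formula: C9H13N3O4S
    rules:
      - product: thiourea-ribose analog
        mechanism: C6-aminopyrazole-loss
        leaving_group: 3-aminopyrazole
        delta: {"C": -3, "H": -1, "N": -1}
        dose_response: {ec50: 70.0, slope: 6.0, ceiling: 1.0}
  - code: s2U
    name: 2-thiouridine
    formula: C9H12N2O5S
  - code: ac4C
    name: N4-acetylcytidine
    formula: C11H15N3O6
    rules:
      - product: C
        mechanism: deacetylation
        leaving_group: acetyl (as acethydrazide)
        delta: {"C": -2, "H": -2, "O": -1}
        dose_response: {ec50: 9.0, slope: 3.0, ceiling: 1.0}
  - code: D
    name: dihydrouridine
    formula: C9H14N2O6
    rules:
      - product: ring-opened C4-hydrazide
        mechanism: ring-open-hydrazide
        delta: {"N": 2, "H": 4}
        dose_response: {ec50: 10.0, slope: 3.0, ceiling: 1.0}
  - code: acp3U
    name: 3-(3-amino-3-carboxypropyl)uridine
    formula: C13H19N3O8
    rules:
      - product: urea-ribose (N-acp)
        mechanism: C6-pyrazolone-loss
        leaving_group: pyrazolone
        delta: {"C": -3, "O": -1}
        dose_response: {ec50: 36.7, slope: 2.0, ceiling: 1.0}
  - code: m5U
    name: 5-methyluridine
    formula: C10H14N2O6
  - code: Um
    name: 2'-O-methyluridine
    formula: C10H14N2O6
    rules:
      - product: urea-ribose (2'-O-methyl)
        mechanism: C6-pyrazolone-loss
        leaving_group: pyrazolone
        delta: {"C": -3, "O": -1}
        dose_response: {ec50: 50.0, slope: 1.83, ceiling: 0.5}
  - code: Cm
    name: 2'-O-methylcytidine
    formula: C10H15N3O5
  - code: Gm
    name: 2'-O-methylguanosine
    formula: C11H15N5O5
  - code: Am
    name: 2'-O-methyladenosine
    formula: C11H15N5O4
  - code: m1A
    name: 1-methyladenosine
    formula: C11H15N5O4
  - code: m1G
    name: 1-methylguanosine
    formula: C11H15N5O5
  - code: m2G
    name: 2-methylguanosine
    formula: C11H15N5O5
  - code: m22G
    name: 2,2-dimethylguanosine
    formula: C12H17N5O5
  - code: m1I
    name: 1-methylinosine
    formula: C11H14N4O5
  - code: I
    name: inosine
    formula: C10H12N4O5
  - code: "Y"
    name: wybutosine
    formula: C21H28N6O9
  - code: t6A
    name: N6-threonylcarbamoyladenosine
    formula: C15H20N6O8
    profile_rules:
      ecoli:
        - product: unknown
          mechanism: unknown-loss
          dose_response: {ec50: 5.0, slope: 2.0, ceiling: 1.0}
  - code: i6A
    name: N6-isopentenyladenosine
    formula: C15H21N5O4
  - code: Q
    name: queuosine
    formula: C17H23N5O7
  - code: mcm5s2U
    name: 5-methoxycarbonylmethyl-2-thiouridine
    formula: C12H16N2O7S
    rules:
      - product: unknown
        mechanism: unknown-loss
        dose_response: {ec50: 3.0, slope: 3.0, ceiling: 1.0}
  - code: ncm5U
    name: 5-carbamoylmethyluridine
    formula: C11H15N3O7
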