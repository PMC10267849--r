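# Default PK parameter sets (rate constants 1/min, V1 in litres).
# Population three-compartment disposition models with effect-site
# equilibration, of the kind validated for intraoperative opioid dosing in
# the anesthesia literature. These are configuration values: swap in your
# preferred parameterization per drug without touching code.
fentanyl:
  V1: 6.09
  k10: 0.0827
  k12: 0.4710
  k21: 0.1020
  k13: 0.2250
  k31: 0.0060
  ke0: 0.1470
  n_compartments: 3
hydromorphone:
  V1: 24.4
  k10: 0.0967
  k12: 0.1386
  k21: 0.0300
  k13: 0.0149
  k31: 0.0037
  ke0: 0.0290
  n_compartments: 3
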