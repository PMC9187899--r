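{
  "version": "sofa-1996/sic-2017",
  "sofa": {
    "respiration_pf": {"direction": "lower_worse", "cutoffs": [400, 300, 200, 100]},
    "coagulation_platelets": {"direction": "lower_worse", "cutoffs": [150, 100, 50, 20]},
    "liver_bilirubin": {"direction": "higher_worse", "cutoffs": [1.2, 2.0, 6.0, 12.0]},
    "cardiovascular_map": {"direction": "lower_worse", "cutoffs": [70]},
    "cns_gcs": {"direction": "lower_worse", "cutoffs": [15, 13, 10, 6]},
    "renal_creatinine": {"direction": "higher_worse", "cutoffs": [1.2, 2.0, 3.5, 5.0]}
  },
  "sic": {
    "platelets": {"direction": "lower_worse", "cutoffs": [150, 100]},
    "inr": {"direction": "higher_worse", "cutoffs": [1.2, 1.4]},
    "sofa_subtotal": {"direction": "higher_worse", "cutoffs": [1, 2]}
  }
}
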