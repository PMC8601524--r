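{
  "comment": "CTCAE v5.0 value-based grade bounds. Bins in canonical units (haemoglobin g/dL, counts 10^9/L); haemoglobin LLN in mmol/L (converted internally with hgb_conversion). Values at or above the LLN are grade 0; haemoglobin grade 4 is a clinical criterion, so value-based anaemia grading caps at grade 3.",
  "bins": {
    "haemoglobin": [8.0, 10.0],
    "leucocytes": [1.0, 2.0, 3.0],
    "neutrophils": [0.5, 1.0, 1.5],
    "platelets": [25, 50, 75]
  },
  "lln": {
    "haemoglobin": {"male": 8.5, "female": 7.5},
    "leucocytes": 4.0,
    "neutrophils": 1.5,
    "platelets": 150
  },
  "hgb_conversion": 1.6113
}
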