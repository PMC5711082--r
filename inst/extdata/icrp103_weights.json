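{
  "name": "icrp103",
  "source": "ICRP Publication 103 (2007), Table 3 tissue weighting factors",
  "weights": {
    "red_bone_marrow": 0.12,
    "colon": 0.12,
    "lung": 0.12,
    "stomach": 0.12,
    "breasts": 0.12,
    "gonads": 0.08,
    "bladder": 0.04,
    "oesophagus": 0.04,
    "liver": 0.04,
    "thyroid": 0.04,
    "bone_surface": 0.01,
    "brain": 0.01,
    "salivary_glands": 0.01,
    "skin": 0.01
  },
  "remainder_weight": 0.12,
  "remainder_tissues": [
    "adrenals",
    "extrathoracic_region",
    "gall_bladder",
    "heart",
    "kidneys",
    "lymphatic_nodes",
    "muscle",
    "oral_mucosa",
    "pancreas",
    "prostate",
    "small_intestine",
    "spleen",
    "thymus",
    "uterus"
  ]
}
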