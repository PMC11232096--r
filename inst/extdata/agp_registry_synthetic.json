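{
  "variants": [
    {
      "name": "AGP1*F1",
      "backbone_mass_Da": 21540.00,
      "modifications": ["pyroglutamate"],
      "prior_abundance": 0.56
    },
    {
      "name": "AGP1*F2",
      "backbone_mass_Da": 21582.08,
      "modifications": ["pyroglutamate"],
      "prior_abundance": 0.03
    },
    {
      "name": "AGP1*S",
      "backbone_mass_Da": 21568.06,
      "modifications": ["pyroglutamate"],
      "prior_abundance": 0.32
    },
    {
      "name": "AGP2",
      "backbone_mass_Da": 21700.10,
      "modifications": ["pyroglutamate", "cysteinylation"],
      "prior_abundance": 0.09
    }
  ]
}
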