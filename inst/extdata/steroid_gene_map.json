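{
  "cortisol": {
    "producing": ["CYP11A1", "CYP17A1", "CYP21A2", "CYP11B1", "HSD11B1"],
    "receptor": ["NR3C1"]
  },
  "cortisone": {
    "producing": ["CYP11A1", "CYP17A1", "CYP21A2", "CYP11B1", "HSD11B2"],
    "receptor": ["NR3C1"]
  },
  "corticosterone": {
    "producing": ["CYP11A1", "CYP21A2", "CYP11B1"],
    "receptor": ["NR3C1", "NR3C2"]
  },
  "aldosterone": {
    "producing": ["CYP11A1", "CYP21A2", "CYP11B2"],
    "receptor": ["NR3C2"]
  },
  "pregnenolone": {
    "producing": ["CYP11A1"],
    "receptor": []
  },
  "progesterone": {
    "producing": ["CYP11A1", "HSD3B1", "HSD3B2"],
    "receptor": ["PGR"]
  },
  "DHEA": {
    "producing": ["CYP11A1", "CYP17A1"],
    "receptor": ["AR"]
  },
  "androstenedione": {
    "producing": ["CYP17A1", "HSD3B2"],
    "receptor": ["AR"]
  },
  "testosterone": {
    "producing": ["CYP17A1", "HSD17B3"],
    "receptor": ["AR"]
  },
  "dihydrotestosterone": {
    "producing": ["SRD5A1", "SRD5A2"],
    "receptor": ["AR"]
  },
  "estrone": {
    "producing": ["CYP19A1", "HSD17B1"],
    "receptor": ["ESR1", "ESR2"]
  },
  "estradiol": {
    "producing": ["CYP19A1", "HSD17B1"],
    "receptor": ["ESR1", "ESR2"]
  }
}
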