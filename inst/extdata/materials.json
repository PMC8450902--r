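{
  "POPC":         {"formula": "C42H82NO8P", "volume": 1256},
  "d31-POPC":     {"formula": "C42H51D31NO8P", "volume": 1256},
  "PC-head":      {"formula": "C10H18NO8P", "volume": 332, "sld": 1.79},
  "PO-tails":     {"formula": "C32H64", "volume": 923, "sld": -0.29},
  "d31-PO-tails": {"formula": "C32H33D31", "volume": 923, "sld": 3.16},
  "caffeine":     {"formula": "C8H10N4O2", "volume": 194, "sld": 3.3},
  "SiO2":         {"formula": "SiO2", "volume": 45.4},
  "Si":           {"formula": "Si", "volume": 20.0}
}
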