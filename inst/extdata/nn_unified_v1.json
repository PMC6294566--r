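{
  "name": "unified-DNA-NN",
  "version": "1.0",
  "source_note": "Unified oligonucleotide nearest-neighbor set (1 M NaCl reference) with hairpin-loop increments at 37C; dH in kcal/mol, dS in cal/(mol K), dG37 in kcal/mol.",
  "stacks": {
    "AA": {"dH": -7.9, "dS": -22.2},
    "AT": {"dH": -7.2, "dS": -20.4},
    "TA": {"dH": -7.2, "dS": -21.3},
    "CA": {"dH": -8.5, "dS": -22.7},
    "GT": {"dH": -8.4, "dS": -22.4},
    "CT": {"dH": -7.8, "dS": -21.0},
    "GA": {"dH": -8.2, "dS": -22.2},
    "CG": {"dH": -10.6, "dS": -27.2},
    "GC": {"dH": -9.8, "dS": -24.4},
    "GG": {"dH": -8.0, "dS": -19.9},
    "TT": {"dH": -7.9, "dS": -22.2},
    "TG": {"dH": -8.5, "dS": -22.7},
    "AC": {"dH": -8.4, "dS": -22.4},
    "AG": {"dH": -7.8, "dS": -21.0},
    "TC": {"dH": -8.2, "dS": -22.2},
    "CC": {"dH": -8.0, "dS": -19.9}
  },
  "terminal_AT_penalty": {"dH": 2.2, "dS": 6.9},
  "hairpin_closing_AT_dG37": 0.5,
  "hairpin_loop_dG37": {
    "3": 3.5, "4": 3.5, "5": 3.3, "6": 4.0, "7": 4.2, "8": 4.3,
    "9": 4.5, "10": 4.4, "12": 4.6, "14": 4.7, "16": 4.9, "18": 4.9,
    "20": 5.1, "25": 5.3, "30": 5.6
  },
  "loop_extrapolation_coefficient": 2.44,
  "loop_reference_temperature_K": 310.15,
  "gas_constant_kcal": 0.001987,
  "salt_dS_coefficient": 0.368,
  "mg_to_monovalent_factor": 3.3
}
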