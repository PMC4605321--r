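{
  "_comment": [
    "Nearest-neighbour standard free energies dG37 (kcal/mol) at 1 M NaCl, 37 C.",
    "dna_dna: unified DNA:DNA parameters (SantaLucia 1998, PNAS 95:1460); the 10",
    "unique doublets are listed, reverse-complement orientations resolve to them.",
    "rna_dna: RNA:DNA hybrid parameters (Sugimoto et al. 1995, Biochemistry",
    "34:11211); keys are RNA top strand 5'->3' over the complementary DNA bottom",
    "strand 3'->5'; all 16 doublets are listed.",
    "dg_init: duplex initiation correction applied to whole-duplex hybrid binding",
    "energies. Note: the published hybrid initiation term is +3.1 kcal/mol",
    "(destabilizing); this configuration deliberately carries -3.1, the value used",
    "by the strand-invasion model this package implements. It is data, not code:",
    "swap the sign here if the conventional penalty is wanted.",
    "Sign convention: more negative = more stable."
  ],
  "dna_dna": {
    "AA/TT": -1.00,
    "AT/TA": -0.88,
    "TA/AT": -0.58,
    "CA/GT": -1.45,
    "GT/CA": -1.44,
    "CT/GA": -1.28,
    "GA/CT": -1.30,
    "CG/GC": -2.17,
    "GC/CG": -2.24,
    "GG/CC": -1.84
  },
  "rna_dna": {
    "AA/TT": -1.0,
    "AC/TG": -2.1,
    "AG/TC": -1.8,
    "AU/TA": -0.9,
    "CA/GT": -0.9,
    "CC/GG": -2.1,
    "CG/GC": -1.7,
    "CU/GA": -0.9,
    "GA/CT": -1.3,
    "GC/CG": -2.7,
    "GG/CC": -2.9,
    "GU/CA": -1.1,
    "UA/AT": -0.6,
    "UC/AG": -1.5,
    "UG/AC": -1.6,
    "UU/AA": -0.2
  },
  "dg_init": -3.1,
  "temperature_K": 310.15,
  "R_kcal": 0.001987,
  "salt_label": "1 M NaCl"
}
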