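{
  "_comment": [
    "SYNTHETIC mismatch parameterization for RNA:DNA hybrid stacks containing a",
    "single internal mismatch of type rG.dG, rC.dC, rA.dA or rU.dT.",
    "A mismatch-containing stack is scored as the Watson-Crick hybrid stack of",
    "the guide doublet plus the per-type offset below (kcal/mol, destabilizing),",
    "applied to each of the (up to) two stacks flanking the mismatched position.",
    "The offsets are NOT literature nearest-neighbour values: they are a",
    "synthetic stand-in calibrated so that one internal mismatch destabilizes a",
    "20-mer hybrid by ~1.5 kcal/mol on average (~6% of its binding free energy,",
    "equivalently a Tm drop of roughly 1.7 C), the destabilization scale reported",
    "for these four mismatch types, with rG.dG the most tolerated and rC.dC the",
    "least. Replace this file with a context-resolved experimental table to use",
    "measured mismatch thermodynamics."
  ],
  "mismatch_offsets": {
    "rG.dG": 0.45,
    "rU.dT": 0.70,
    "rA.dA": 0.90,
    "rC.dC": 1.05
  }
}
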