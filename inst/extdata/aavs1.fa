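>AAVS1_protospacer guide-matching strand, 5'->3', 20 bp, PAM TGG follows the 3' end; the 20-nt sgRNA is its RNA transcript, the tru-gRNA drops the two 5' (PAM-distal) nucleotides
GGGGCCACTAGGGACAGGAT
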