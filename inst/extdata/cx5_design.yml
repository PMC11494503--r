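# Default CX5 SICLOPPS library design.
# The anchors below are SYNTHETIC stand-ins for the intein-flanking
# sequences of a real construct; they are used by the simulator and the
# test suite. Replace both anchors with the 3' end of your C-intein CDS
# and the 5' start of your N-intein CDS before analyzing real data.
upstream_anchor: GGTTCTCATAACGCTCGCGAT
downstream_anchor: TGCTTAAGTACCGGTGAAGCT
n6_length: 6
fixed_first_codons: [TGT, TGC]
n_variable: 5
variable_codon_scheme: NNS
max_anchor_mismatch: 1
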