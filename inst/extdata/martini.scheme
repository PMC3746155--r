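# Coarse-grained (MARTINI-style) lipid segment scheme.
# Columns: residue particle segment
# Segments: head_terminal (choline/ethanolamine), phosphate, glycerol, tail.

# DMPC (diC14:0-phosphatidylcholine)
DMPC NC3 head_terminal
DMPC PO4 phosphate
DMPC GL1 glycerol
DMPC GL2 glycerol
DMPC C1A tail
DMPC C2A tail
DMPC C3A tail
DMPC C1B tail
DMPC C2B tail
DMPC C3B tail

# DPPC (diC16:0-phosphatidylcholine)
DPPC NC3 head_terminal
DPPC PO4 phosphate
DPPC GL1 glycerol
DPPC GL2 glycerol
DPPC C1A tail
DPPC C2A tail
DPPC C3A tail
DPPC C4A tail
DPPC C1B tail
DPPC C2B tail
DPPC C3B tail
DPPC C4B tail

# DSPE (diC18:0-phosphatidylethanolamine); the terminal amine plays the
# head_terminal part that choline plays in the PCs
DSPE NH3 head_terminal
DSPE PO4 phosphate
DSPE GL1 glycerol
DSPE GL2 glycerol
DSPE C1A tail
DSPE C2A tail
DSPE C3A tail
DSPE C4A tail
DSPE C1B tail
DSPE C2B tail
DSPE C3B tail
DSPE C4B tail

# residue-name dialects (3-character PDB fields)
alias DMP DMPC
alias DPP DPPC
alias DSP DSPE

# coarse-grained water
role W solvent
role ION other
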