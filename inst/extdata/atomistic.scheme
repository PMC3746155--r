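# Atomistic (heavy-atom) lipid segment scheme, CHARMM-style naming.
# Columns: residue particle segment

# DMPC (diC14:0-PC)
DMPC N head_terminal
DMPC C11 head_terminal
DMPC C12 head_terminal
DMPC C13 head_terminal
DMPC C14 head_terminal
DMPC C15 head_terminal
DMPC P phosphate
DMPC O11 phosphate
DMPC O12 phosphate
DMPC O13 phosphate
DMPC O14 phosphate
DMPC C1 glycerol
DMPC C2 glycerol
DMPC C3 glycerol
DMPC O21 glycerol
DMPC O22 glycerol
DMPC O31 glycerol
DMPC O32 glycerol
DMPC C21 glycerol
DMPC C31 glycerol
DMPC C22 tail
DMPC C23 tail
DMPC C24 tail
DMPC C25 tail
DMPC C26 tail
DMPC C27 tail
DMPC C28 tail
DMPC C29 tail
DMPC C210 tail
DMPC C211 tail
DMPC C212 tail
DMPC C213 tail
DMPC C214 tail
DMPC C32 tail
DMPC C33 tail
DMPC C34 tail
DMPC C35 tail
DMPC C36 tail
DMPC C37 tail
DMPC C38 tail
DMPC C39 tail
DMPC C310 tail
DMPC C311 tail
DMPC C312 tail
DMPC C313 tail
DMPC C314 tail

# DSPE (diC18:0-PE); terminal ethanolamine amine = head_terminal
DSPE N head_terminal
DSPE C11 head_terminal
DSPE C12 head_terminal
DSPE P phosphate
DSPE O11 phosphate
DSPE O12 phosphate
DSPE O13 phosphate
DSPE O14 phosphate
DSPE C1 glycerol
DSPE C2 glycerol
DSPE C3 glycerol
DSPE O21 glycerol
DSPE O22 glycerol
DSPE O31 glycerol
DSPE O32 glycerol
DSPE C21 glycerol
DSPE C31 glycerol
DSPE C22 tail
DSPE C23 tail
DSPE C24 tail
DSPE C25 tail
DSPE C26 tail
DSPE C27 tail
DSPE C28 tail
DSPE C29 tail
DSPE C210 tail
DSPE C211 tail
DSPE C212 tail
DSPE C213 tail
DSPE C214 tail
DSPE C215 tail
DSPE C216 tail
DSPE C217 tail
DSPE C218 tail
DSPE C32 tail
DSPE C33 tail
DSPE C34 tail
DSPE C35 tail
DSPE C36 tail
DSPE C37 tail
DSPE C38 tail
DSPE C39 tail
DSPE C310 tail
DSPE C311 tail
DSPE C312 tail
DSPE C313 tail
DSPE C314 tail
DSPE C315 tail
DSPE C316 tail
DSPE C317 tail
DSPE C318 tail

# DPPC (diC16:0-PC)
DPPC N head_terminal
DPPC C11 head_terminal
DPPC C12 head_terminal
DPPC C13 head_terminal
DPPC C14 head_terminal
DPPC C15 head_terminal
DPPC P phosphate
DPPC O11 phosphate
DPPC O12 phosphate
DPPC O13 phosphate
DPPC O14 phosphate
DPPC C1 glycerol
DPPC C2 glycerol
DPPC C3 glycerol
DPPC O21 glycerol
DPPC O22 glycerol
DPPC O31 glycerol
DPPC O32 glycerol
DPPC C21 glycerol
DPPC C31 glycerol
DPPC C22 tail
DPPC C23 tail
DPPC C24 tail
DPPC C25 tail
DPPC C26 tail
DPPC C27 tail
DPPC C28 tail
DPPC C29 tail
DPPC C210 tail
DPPC C211 tail
DPPC C212 tail
DPPC C213 tail
DPPC C214 tail
DPPC C215 tail
DPPC C216 tail
DPPC C32 tail
DPPC C33 tail
DPPC C34 tail
DPPC C35 tail
DPPC C36 tail
DPPC C37 tail
DPPC C38 tail
DPPC C39 tail
DPPC C310 tail
DPPC C311 tail
DPPC C312 tail
DPPC C313 tail
DPPC C314 tail
DPPC C315 tail
DPPC C316 tail

alias DMP DMPC
alias DPP DPPC
alias DSP DSPE

role HOH solvent
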