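# Interaction-type parameter table, version 1.
# radius: van der Waals radius (Angstrom) used for the surface distance d = r - R_i - R_j.
# hydrophobic_if_apolar: carbon is hydrophobic unless bonded to N or O; halogens always hydrophobic.
# donor_rule: N/O with at least one attached hydrogen donate; acceptor_rule: N/O always accept.
element,radius,hydrophobic,donor_if_h,acceptor
C,1.9,apolar_only,FALSE,FALSE
N,1.8,FALSE,TRUE,TRUE
O,1.7,FALSE,TRUE,TRUE
S,2.0,FALSE,FALSE,FALSE
P,2.1,FALSE,FALSE,FALSE
F,1.5,TRUE,FALSE,FALSE
Cl,1.8,TRUE,FALSE,FALSE
Br,2.0,TRUE,FALSE,FALSE
I,2.2,TRUE,FALSE,FALSE
H,0.0,FALSE,FALSE,FALSE
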