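>IgA1 proline-rich hinge-region synthetic peptide
VTVPVPSTPPTPSPSTPPTPSPS
>EPO O-glycosylation region synthetic peptide
AQKEAISPPDAASAA
>ArtV1 C-terminal extensin-like synthetic peptide
AAGGSPSPPADGGSPPPPADG
>STRUBBELIG synthetic peptide
DGTPFNTSIITPPPPPCCDPPPATHR
>Internal standard peptide for kinetics assays
PTTTPITTTTTVTPTPTPTGTQTK
>IgA1 hinge-region tryptic peptide (carbamidomethylated Cys)
HYTNPSQDVTVPCPVPSTPPTPSPSTPPTPSPSCCHPR
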