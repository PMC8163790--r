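protein_id	origin
HBA	erythrocyte
HBB-B1	erythrocyte
HBZ	erythrocyte
CA1	erythrocyte
CA2	erythrocyte
BPGM	erythrocyte
BLVRB	erythrocyte
PRDX2	erythrocyte
PRDX6	erythrocyte
SOD1	erythrocyte
CAT	erythrocyte
ALDOA	erythrocyte
PF4	platelet
PPBP	platelet
THBS1	platelet
ITGA2B	platelet
ITGB3	platelet
VWF	platelet
SELP	platelet
FLNA	platelet
MYH9	platelet
TLN1	platelet
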