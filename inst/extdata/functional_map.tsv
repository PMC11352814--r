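protein_id	category
A2M	hemostasis
F2	hemostasis
F10	hemostasis
F12	hemostasis
PDGFB	hemostasis
PLG	hemostasis
PROZ	hemostasis
PTPN11	hemostasis
TLN1	hemostasis
KNG1	hemostasis
PF4	hemostasis
THBS1	hemostasis
FG	hemostasis
FGA	hemostasis
FGB	hemostasis
FGG	hemostasis
ORM1	hemostasis
VWF	hemostasis
C1QA	complement
C1QC	complement
CFH	complement
CFP	complement
C9	complement
CCL17	cytokine
CXCL9	cytokine
IL1B	cytokine
CSF2	cytokine
CXCL5	cytokine
CCL25	cytokine
IL6	cytokine
IL8	cytokine
TNF	cytokine
IGLV3-10	adaptive-immunity
IGHV2-5	adaptive-immunity
IGKV6-21	adaptive-immunity
IGLV3-25	adaptive-immunity
IGLV6-57	adaptive-immunity
PGLYRP2	other-immune
ATRN	other-immune
GULP1	other-immune
SLC2A(3,14)	other-immune
SLC2A	other-immune
GARIN1B	orphan
GPX3	orphan
IGFALS	orphan
MYL6(B)	orphan
MYL6	orphan
OR5M11	orphan
AFM	orphan
PKHD1	orphan
MDC1	orphan
APOA1	lipid-metabolism
APOB	lipid-metabolism
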