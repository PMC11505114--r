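abbrev	label
ACE	ACE inhibitor
AUP	Activating ubiquitin-mediated proteolysis
API	Acylaminoacyl peptidase inhibitor
AI	Alpha-glucosidase inhibitor
AA	Antiammnestic
AP	Antibacterial peptide
AIN	Anti-inflammatory
ANT	Antioxidative
CALP1	Calpain 1 inhibitor
CaMPDE	CaMPDE inhibitor
DDPI	D-Ala-D-Ala dipeptidase inhibitor
DPPIII	Dipeptidyl peptidase III inhibitor
DPPIV	Dipeptidyl peptidase IV inhibitor
GCI	Glutamate carboxypeptidase inhibitor
HMG-CoA	HMG-CoA reductase inhibitor
HYP	Hypotensive
HYC	Hypouricemic
IMMU	Immunomodulating
ITPII	Inhibitor of tripeptidyl peptidase II
ICAA	Inhibitor of cytosol alanyl aminopeptidase
LACT	Lactocepin inhibitor
LEUC	Leucyltransferase inhibitor
NEPR	Neprilysin 2 inhibitor
NEP	Neuropeptide
PANC	Pancreatic lipase inhibitor
PHOS	Phospholipase A2 inhibitor
REG	Regulating (phosphoglycerate kinase activity)
RENIN	Renin inhibitor
STIG	Stimulating (glucose uptake stimulating peptide)
STIV	Stimulating (vasoactive substance release)
TTL	Tubulin-tyrosine ligase inhibitor
XAAP	Xaa-Pro inhibitor
AAMY	Alpha-amylase inhibitor
CTX	Celiac toxic
OPI	Opioid
IST	Immunostimulating
ACPI	Alanine carboxypeptidase inhibitor
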