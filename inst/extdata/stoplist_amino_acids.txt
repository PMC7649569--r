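# Three-letter amino-acid codes: frequent OCR words in figures that collide
# with gene aliases. Off by default; enable via the stoplist argument.
ALA
ARG
ASN
ASP
CYS
GLN
GLU
GLY
HIS
ILE
LEU
LYS
MET
PHE
PRO
SER
THR
TRP
TYR
VAL
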