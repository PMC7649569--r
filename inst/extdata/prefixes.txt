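# Decoration prefixes stripped from OCR words (one per line, trailing "-" implied part of the prefix)
P-
PP-
PHOSPHO-
AC-
MYC-
HA-
GST-
GFP-
FLAG-
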