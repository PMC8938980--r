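abbrev,full_name
AMY,Amygdala
CB,Cerebellum
HB,Hindbrain
HPF,Hippocampal formation
HY,Hypothalamus
ISO,Isocortex
MB,Midbrain
MY,Medulla
OLF,Olfactory bulbs
PAL,Pallidum
STR,Striatum
TH,Thalamus
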