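abbrev,full_name
ACA,Anterior cingulate area
ACB,Nucleus accumbens
AHN,Anterior hypothalamic nucleus
AON,Anterior olfactory nucleus
ATN,Anterior dorsal thalamus
CA1,Field CA1
CA2,Field CA2
CA3,Field CA3
DG,Dentate gyrus
DMH,Dorsomedial hypothalamus
DMX,Dorsal motor nucleus of the vagus nerve
EPI,Epithalamus
FN,Fastigial nucleus
FRP,Frontal pole
GRN,Gigantocellular reticular nucleus
IC,Inferior colliculus
ILM,Intralaminar nucleus
IO,Inferior olivary complex
IRN,Intermediate reticular nucleus
LDT,Laterodorsal tegmental nucleus
LS,Lateral septum
MARN,Magnocellular reticular nucleus
MDRN,Medullary reticular nucleus
MED,Medial dorsal thalamus
MO,Somatomotor areas
MOB,Main olfactory bulb
MPN,Medial preoptic nucleus
MPO,Medial preoptic area
MRN,Midbrain reticular nucleus
NTS,Nucleus of the solitary tract
ORB,Orbital area
OT,Olfactory tubercle
PAG,Periaqueductal gray
PALc,Caudal pallidum
PALm,Medial pallidum
PALv,Ventral pallidum
PCG,Pontine central gray
PG,Pontine gray
PH,Posterior hypothalamus
PHY,Perihypoglossal nucleus
PMd,Dorsal premammilary
PMv,Ventral premammilary
PRN,Pontine reticular nucleus
PRT,Pretectal region
PVH,Paraventricular hypothalamus
RCH,Retrochiasmatic area
RN,Red nucleus
RSP,Retrosplenial cortex
RT,Reticular nucleus of the thalamus
SCm,Motor superior colliculus
SCs,Sensory superior colliculus
SF,Septofimbrial nucleus
SOC,Superior olivary complex
SPF,Subparafascicular nucleus
SUB,Subiculum
TRN,Tegmental reticular nucleus
TT,Taenia tecta
VENT,Ventral group of the dorsal thalamus
VERM,Vermal regions
VI,Abducens nucleus
VMH,Ventromedial hypothalamic nucleus
VNC,Vestibular nuclei
VTA,Ventral tegmental area
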