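name	x	y	region
Fp1	-0.30	0.90	frontal
Fp2	0.30	0.90	frontal
F7	-0.80	0.55	frontal
F3	-0.40	0.55	frontal
Fz	0.00	0.55	frontal
F4	0.40	0.55	frontal
F8	0.80	0.55	frontal
FC5	-0.60	0.30	frontal
FC1	-0.20	0.30	frontal
FC2	0.20	0.30	frontal
FC6	0.60	0.30	frontal
A1	-0.95	0.00	temporal
T7	-0.80	0.00	temporal
T8	0.80	0.00	temporal
A2	0.95	0.00	temporal
C3	-0.40	0.00	central
Cz	0.00	0.00	central
C4	0.40	0.00	central
CP5	-0.60	-0.30	central
CP1	-0.20	-0.30	central
CP2	0.20	-0.30	central
CP6	0.60	-0.30	central
P7	-0.80	-0.55	parietal
P3	-0.40	-0.55	parietal
Pz	0.00	-0.55	parietal
P4	0.40	-0.55	parietal
P8	0.80	-0.55	parietal
PO3	-0.30	-0.75	parietal
PO4	0.30	-0.75	parietal
O1	-0.30	-0.90	occipital
Oz	0.00	-0.90	occipital
O2	0.30	-0.90	occipital
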