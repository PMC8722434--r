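from	to
Fp1	Fp2
Fp1	F7
Fp1	F3
Fp2	F4
Fp2	F8
F7	F3
F7	FC5
F7	T7
F7	A1
F3	Fz
F3	FC5
F3	FC1
Fz	F4
Fz	FC1
Fz	FC2
F4	F8
F4	FC2
F4	FC6
F8	FC6
F8	T8
F8	A2
FC5	C3
FC5	T7
FC1	C3
FC1	Cz
FC2	Cz
FC2	C4
FC6	C4
FC6	T8
A1	T7
A1	P7
T7	C3
T7	CP5
T7	P7
C3	Cz
C3	CP5
C3	CP1
Cz	C4
Cz	CP1
Cz	CP2
C4	CP2
C4	CP6
T8	A2
T8	CP6
T8	P8
A2	P8
CP5	P7
CP5	P3
CP1	P3
CP1	Pz
CP2	Pz
CP2	P4
CP6	P4
CP6	P8
P7	P3
P3	Pz
P3	PO3
Pz	P4
Pz	PO3
Pz	PO4
P4	P8
P4	PO4
P8	PO4
PO3	O1
PO3	Oz
PO4	Oz
PO4	O2
O1	Oz
Oz	O2
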