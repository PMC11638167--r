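name	x	y	z
FC5	-0.756469	0.342798	0.556996
FC3	-0.543523	0.362291	0.757184
FC1	-0.283943	0.350699	0.892405
FCZ	0	0.309017	0.951057
FC2	0.283943	0.350699	0.892405
FC4	0.543523	0.362291	0.757184
FC6	0.756469	0.342798	0.556996
C5	-0.809017	0	0.587785
C3	-0.587785	0	0.809017
C1	-0.309017	0	0.951057
CZ	0	0	1
C2	0.309017	0	0.951057
C4	0.587785	0	0.809017
C6	0.809017	0	0.587785
CP5	-0.756469	-0.342798	0.556996
CP3	-0.543523	-0.362291	0.757184
CP1	-0.283943	-0.350699	0.892405
CPZ	0	-0.309017	0.951057
CP2	0.283943	-0.350699	0.892405
CP4	0.543523	-0.362291	0.757184
CP6	0.756469	-0.342798	0.556996
FP1	-0.293893	0.904508	0.309017
FPZ	0	0.951057	0.309017
FP2	0.293893	0.904508	0.309017
AF7	-0.559017	0.769421	0.309017
AF3	-0.294292	0.830962	0.472118
AFZ	0	0.809017	0.587785
AF4	0.294292	0.830962	0.472118
AF8	0.559017	0.769421	0.309017
F7	-0.769421	0.559017	0.309017
F5	-0.618731	0.619753	0.482782
F3	-0.433027	0.645416	0.629226
F1	-0.222818	0.634556	0.740062
FZ	0	0.587785	0.809017
F2	0.222818	0.634556	0.740062
F4	0.433027	0.645416	0.629226
F6	0.618731	0.619753	0.482782
F8	0.769421	0.559017	0.309017
FT7	-0.904508	0.293893	0.309017
FT8	0.904508	0.293893	0.309017
T7	-0.951057	0	0.309017
T8	0.951057	0	0.309017
T9	-1	0	0
T10	1	0	0
TP7	-0.904508	-0.293893	0.309017
TP8	0.904508	-0.293893	0.309017
P7	-0.769421	-0.559017	0.309017
P5	-0.618731	-0.619753	0.482782
P3	-0.433027	-0.645416	0.629226
P1	-0.222818	-0.634556	0.740062
PZ	0	-0.587785	0.809017
P2	0.222818	-0.634556	0.740062
P4	0.433027	-0.645416	0.629226
P6	0.618731	-0.619753	0.482782
P8	0.769421	-0.559017	0.309017
PO7	-0.559017	-0.769421	0.309017
PO3	-0.294292	-0.830962	0.472118
POZ	0	-0.809017	0.587785
PO4	0.294292	-0.830962	0.472118
PO8	0.559017	-0.769421	0.309017
O1	-0.293893	-0.904508	0.309017
OZ	0	-0.951057	0.309017
O2	0.293893	-0.904508	0.309017
IZ	0	-1	0
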