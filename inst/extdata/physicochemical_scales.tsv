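aa	hydrophilicity	flexibility	accessibility	polarity	exposed_surface	turns
A	2.1	1.041	0.49	8.1	27.8	0.66
C	1.4	0.960	0.26	5.5	15.5	1.19
D	10.0	1.033	0.81	13.0	60.6	1.46
E	7.8	1.094	0.84	12.3	68.2	0.74
F	-9.2	0.930	0.42	5.2	25.5	0.60
G	5.7	1.142	0.48	9.0	24.5	1.56
H	2.1	0.982	0.66	10.4	50.7	0.95
I	-8.0	1.002	0.34	5.2	22.8	0.47
K	5.7	1.093	0.97	11.3	103.0	1.01
L	-9.2	0.967	0.40	4.9	27.6	0.59
M	-4.2	0.947	0.48	5.7	33.5	0.60
N	7.0	1.117	0.78	11.6	60.1	1.56
P	2.1	1.055	0.75	8.0	51.5	1.52
Q	6.0	1.165	0.84	10.5	68.7	0.98
R	4.2	1.038	0.95	10.5	94.7	0.95
S	6.5	1.169	0.65	9.2	42.0	1.43
T	5.2	1.073	0.70	8.6	45.0	0.96
V	-3.7	0.982	0.36	5.9	23.7	0.50
W	-10.0	0.925	0.51	5.4	34.7	0.96
Y	-1.9	0.961	0.76	6.2	55.2	1.14
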