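	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.160000	-0.210123	1.004691	1.004691	-0.224198	0.155062	0.901728	-0.220000	1.148889	-0.239012	-0.168642	1.004691	0.427654	1.004691	1.380000	0.238025	0.216543	-0.231111	0.260000	0.352840
C	-0.210123	-0.308642	1.320988	1.320988	-0.343457	0.257037	1.197284	-0.456790	1.492840	-0.427407	-0.225679	1.320988	0.612593	1.320988	1.765432	0.367654	0.339259	-0.447160	0.396543	0.517037
D	1.004691	1.320988	-0.604938	-0.604938	1.463951	0.168148	-0.550864	2.358025	-0.670123	1.972593	1.048395	-0.604938	-0.187407	-0.604938	-0.753086	0.041728	0.072593	2.189877	0.011358	-0.105185
E	1.004691	1.320988	-0.604938	-0.604938	1.463951	0.168148	-0.550864	2.358025	-0.670123	1.972593	1.048395	-0.604938	-0.187407	-0.604938	-0.753086	0.041728	0.072593	2.189877	0.011358	-0.105185
F	-0.224198	-0.343457	1.463951	1.463951	-0.387160	0.308148	1.331358	-0.550864	1.647654	-0.500741	-0.242716	1.463951	0.699259	1.463951	1.938025	0.430617	0.399259	-0.532346	0.462469	0.594815
G	0.155062	0.257037	0.168148	0.168148	0.308148	-0.007901	0.130370	0.681728	0.225432	0.510617	0.168148	0.168148	0.003951	0.168148	0.326173	-0.011852	-0.011605	0.605432	-0.011605	-0.005679
H	0.901728	1.197284	-0.550864	-0.550864	1.331358	0.130370	-0.505679	2.175062	-0.604198	1.810370	0.942469	-0.550864	-0.189630	-0.550864	-0.669383	0.015802	0.043704	2.015802	-0.011605	-0.116296
I	-0.220000	-0.456790	2.358025	2.358025	-0.550864	0.681728	2.175062	-1.000000	2.608889	-0.832346	-0.255309	2.358025	1.274321	2.358025	3.000000	0.871358	0.823210	-0.931111	0.920000	1.119506
K	1.148889	1.492840	-0.670123	-0.670123	1.647654	0.225432	-0.604198	2.608889	-0.751111	2.195802	1.196543	-0.670123	-0.177531	-0.670123	-0.857778	0.083210	0.118025	2.428889	0.048889	-0.083457
L	-0.239012	-0.427407	1.972593	1.972593	-0.500741	0.510617	1.810370	-0.832346	2.195802	-0.713086	-0.267407	1.972593	1.020247	1.972593	2.545432	0.672593	0.631358	-0.784198	0.714321	0.886173
M	-0.168642	-0.225679	1.048395	1.048395	-0.242716	0.168148	0.942469	-0.255309	1.196543	-0.267407	-0.178272	1.048395	0.452593	1.048395	1.433580	0.255062	0.232593	-0.263457	0.278025	0.374815
N	1.004691	1.320988	-0.604938	-0.604938	1.463951	0.168148	-0.550864	2.358025	-0.670123	1.972593	1.048395	-0.604938	-0.187407	-0.604938	-0.753086	0.041728	0.072593	2.189877	0.011358	-0.105185
P	0.427654	0.612593	-0.187407	-0.187407	0.699259	0.003951	-0.189630	1.274321	-0.177531	1.020247	0.452593	-0.187407	-0.126420	-0.187407	-0.147901	-0.047407	-0.035309	1.162469	-0.059012	-0.100494
Q	1.004691	1.320988	-0.604938	-0.604938	1.463951	0.168148	-0.550864	2.358025	-0.670123	1.972593	1.048395	-0.604938	-0.187407	-0.604938	-0.753086	0.041728	0.072593	2.189877	0.011358	-0.105185
R	1.380000	1.765432	-0.753086	-0.753086	1.938025	0.326173	-0.669383	3.000000	-0.857778	2.545432	1.433580	-0.753086	-0.147901	-0.753086	-1.000000	0.160247	0.200988	2.802222	0.120000	-0.036049
S	0.238025	0.367654	0.041728	0.041728	0.430617	-0.011852	0.015802	0.871358	0.083210	0.672593	0.255062	0.041728	-0.047407	0.041728	0.160247	-0.031605	-0.027407	0.783210	-0.035309	-0.045185
T	0.216543	0.339259	0.072593	0.072593	0.399259	-0.011605	0.043704	0.823210	0.118025	0.631358	0.232593	0.072593	-0.035309	0.072593	0.200988	-0.027407	-0.024198	0.738025	-0.030123	-0.036049
V	-0.231111	-0.447160	2.189877	2.189877	-0.532346	0.605432	2.015802	-0.931111	2.428889	-0.784198	-0.263457	2.189877	1.162469	2.189877	2.802222	0.783210	0.738025	-0.871111	0.828889	1.016543
W	0.260000	0.396543	0.011358	0.011358	0.462469	-0.011605	-0.011605	0.920000	0.048889	0.714321	0.278025	0.011358	-0.059012	0.011358	0.120000	-0.035309	-0.030123	0.828889	-0.040000	-0.053827
Y	0.352840	0.517037	-0.105185	-0.105185	0.594815	-0.005679	-0.116296	1.119506	-0.083457	0.886173	0.374815	-0.105185	-0.100494	-0.105185	-0.036049	-0.045185	-0.036049	1.016543	-0.053827	-0.083457
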