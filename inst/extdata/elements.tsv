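symbol	vdw_radius	mass	is_metal
H	1.20	1.0080	0
He	1.40	4.0030	0
Li	2.00	6.9410	1
Be	2.00	9.0120	1
B	1.92	10.8120	0
C	1.70	12.0110	0
N	1.55	14.0070	0
O	1.52	15.9990	0
F	1.47	18.9980	0
Ne	1.54	20.1800	0
Na	2.00	22.9900	1
Mg	2.00	24.3050	1
Al	2.00	26.9820	1
Si	2.10	28.0860	0
P	1.80	30.9740	0
S	1.80	32.0670	0
Cl	1.75	35.4530	0
Ar	1.88	39.9480	0
K	2.00	39.0980	1
Ca	2.00	40.0780	1
Sc	2.00	44.9560	1
Ti	2.00	47.8670	1
V	2.00	50.9440	1
Cr	2.00	51.9960	1
Mn	2.00	54.9380	1
Fe	2.00	55.8450	1
Co	2.00	58.9330	1
Ni	2.00	58.6930	1
Cu	2.00	63.5460	1
Zn	2.00	65.3900	1
Ga	2.00	69.7230	1
Ge	2.11	72.6100	0
As	1.85	74.9220	0
Se	1.90	78.9600	0
Br	1.85	79.9040	0
Kr	2.02	83.8000	0
Rb	2.00	85.4680	1
Sr	2.00	87.6200	1
Y	2.00	88.9060	1
Zr	2.00	91.2240	1
Nb	2.00	92.9060	1
Mo	2.00	95.9400	1
Tc	2.00	98.0000	1
Ru	2.00	101.0700	1
Rh	2.00	102.9060	1
Pd	2.00	106.4200	1
Ag	2.00	107.8680	1
Cd	2.00	112.4120	1
In	2.00	114.8180	1
Sn	2.00	118.7110	1
Sb	2.06	121.7600	0
Te	2.06	127.6000	0
I	1.98	126.9040	0
Xe	2.16	131.2900	0
Cs	2.00	132.9050	1
Ba	2.00	137.3280	1
La	2.00	138.9060	1
Ce	2.00	140.1160	1
Pr	2.00	140.9080	1
Nd	2.00	144.2400	1
Pm	2.00	145.0000	1
Sm	2.00	150.3600	1
Eu	2.00	151.9640	1
Gd	2.00	157.2500	1
Tb	2.00	158.9250	1
Dy	2.00	162.5000	1
Ho	2.00	164.9300	1
Er	2.00	167.2600	1
Tm	2.00	168.9340	1
Yb	2.00	173.0400	1
Lu	2.00	174.9670	1
Hf	2.00	178.4900	1
Ta	2.00	180.9480	1
W	2.00	183.8400	1
Re	2.00	186.2070	1
Os	2.00	190.2300	1
Ir	2.00	192.2170	1
Pt	2.00	195.0780	1
Au	2.00	196.9670	1
Hg	2.00	200.5900	1
Tl	2.00	204.3830	1
Pb	2.00	207.2000	1
Bi	2.00	208.9800	1
Po	1.97	209.0000	0
At	2.02	210.0000	0
Rn	2.20	222.0000	0
Fr	2.00	223.0000	1
Ra	2.00	226.0000	1
Ac	2.00	227.0000	1
Th	2.00	232.0380	1
Pa	2.00	231.0360	1
U	2.00	238.0290	1
Np	2.00	237.0000	1
Pu	2.00	244.0000	1
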