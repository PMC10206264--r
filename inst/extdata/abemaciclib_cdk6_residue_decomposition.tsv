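# Reported per-residue decomposition of the abemaciclib/CDK6 binding enthalpy
# (kcal/mol; reference values from the published study this analysis follows).
# subtotal = d_vdW + d_ele + d_GB + d_surf; S/B columns are the side-chain and
# backbone subtotals.
residue	d_vdW	d_ele	d_GB	d_surf	d_subtotal	sidechain_subtotal	backbone_subtotal
I19	-3.67	-0.78	1.77	-0.60	-3.27	-3.59	0.31
V27	-1.70	-0.32	0.22	-0.15	-1.95	-1.78	-0.17
K29	-0.84	-1.71	2.10	-0.08	-0.53	-0.19	-0.34
A41	-1.35	-0.07	0.14	-0.13	-1.40	-1.36	-0.05
K43	-0.81	-7.62	5.36	-0.07	-3.14	-2.77	-0.37
V77	-0.54	0.02	-0.44	-0.03	-0.99	-0.70	-0.28
F98	-1.15	0.03	0.12	-0.08	-1.08	-0.87	-0.21
E99	-0.31	-0.23	2.29	-0.02	1.72	0.08	1.64
H100	-1.49	-1.65	2.08	-0.11	-1.17	0.05	-1.23
V101	-1.07	-0.69	0.90	-0.05	-0.91	-0.76	-0.15
D104	-0.67	-1.46	3.90	-0.13	1.64	1.50	0.14
N150	-0.74	0.45	-0.31	-0.05	-0.65	-0.52	-0.13
L152	-1.66	-0.07	-0.38	-0.25	-2.36	-2.24	-0.12
A162	-0.85	-0.44	0.28	-0.08	-1.09	-0.82	-0.27
D163	-2.02	-0.09	6.25	-0.20	3.94	3.89	0.05
R168	-0.34	0.17	-1.15	-0.01	-1.32	-1.31	-0.01
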