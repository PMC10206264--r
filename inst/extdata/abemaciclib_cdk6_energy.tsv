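# Reported MM/GBSA energy components for the abemaciclib/CDK6 complex
# (kcal/mol; reference values from the published study this analysis follows).
# Delta = Complex - Receptor - Ligand; Egas/Esolv/enthalpy rows are derived.
term	complex	receptor	ligand	delta
E_vdW	-2396.80	-2339.28	-5.83	-51.70
E_ele	-19936.00	-20063.71	155.02	-27.31
E_GB	-3259.72	-3291.36	-19.65	51.29
E_surf	104.35	106.18	4.37	-6.20
T_delta_S	3282.60	3241.42	65.36	-24.18
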