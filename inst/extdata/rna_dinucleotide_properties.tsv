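# Dinucleotide property table for RNA (16 units x 22 properties).
# Content columns count bases in the dinucleotide (Thymine content is
# evaluated on the DNA image of the RNA, i.e. U counted as T).
# Geometry columns are A-form helical base-step averages (degrees /
# Angstrom); thermodynamic columns are nearest-neighbour stacking
# parameters (kcal/mol, entropies in cal/mol/K) from the two standard
# published RNA parameter sets ("... 1" marks the alternative set);
# hydrophilicity columns are the two published dinucleotide scales.
# All columns are z-scored across the 16 dinucleotides before use.
unit	Adenine content	GC content	Purine content	Keto content	Cytosine content	Thymine content	Guanine content	Tilt	Twist	Roll	Rise	Shift	Slide	Stacking energy	Entropy	Entropy 1	Enthalpy	Enthalpy 1	Free energy	Free energy 1	Hydrophilicity	Hydrophilicity 1
AA	2	0	2	0	0	0	0	-0.8	31.0	7.0	3.18	-0.08	-1.27	-0.9	-19.0	-18.4	-6.82	-6.6	-0.93	-1.2	0.023	0.04
AC	1	1	1	0	1	0	0	0.8	32.0	4.8	3.24	0.23	-1.43	-2.1	-29.5	-26.2	-11.40	-10.2	-2.24	-2.4	0.083	0.14
AG	1	1	2	1	0	0	1	0.5	30.0	8.5	3.30	-0.04	-1.50	-1.7	-27.1	-19.2	-10.48	-7.6	-2.08	-2.0	0.035	0.08
AU	1	0	1	1	0	1	0	1.1	33.0	7.1	3.24	-0.06	-1.36	-0.9	-26.7	-15.5	-9.38	-5.7	-1.10	-1.2	0.090	0.14
CA	1	1	1	0	1	0	0	1.0	31.0	9.9	3.09	0.11	-1.46	-1.8	-26.9	-27.8	-10.44	-10.5	-2.11	-2.1	0.118	0.21
CC	0	2	0	0	2	0	0	0.3	32.0	8.7	3.32	-0.01	-1.78	-2.9	-32.7	-29.7	-13.39	-12.2	-3.26	-3.3	0.349	0.49
CG	0	2	1	1	1	0	1	-0.1	27.0	12.1	2.91	0.30	-1.89	-2.0	-26.7	-19.4	-10.64	-8.0	-2.36	-2.4	0.193	0.35
CU	0	1	0	1	1	1	0	0.5	30.0	8.5	3.30	-0.04	-1.50	-1.7	-27.1	-19.2	-10.48	-7.6	-2.08	-2.0	0.378	0.52
GA	1	1	2	1	0	0	1	1.3	32.0	9.4	3.38	0.07	-1.70	-2.3	-32.5	-35.5	-12.44	-13.3	-2.35	-2.7	0.048	0.10
GC	0	2	1	1	1	0	1	0.0	35.0	6.1	3.22	0.07	-1.39	-3.4	-36.9	-34.9	-14.88	-14.2	-3.42	-3.8	0.112	0.19
GG	0	2	2	2	0	0	2	0.3	32.0	8.7	3.32	-0.01	-1.78	-2.9	-32.7	-29.7	-13.39	-12.2	-3.26	-3.3	0.065	0.12
GU	0	1	1	2	0	1	1	0.8	32.0	4.8	3.24	0.23	-1.43	-2.1	-29.5	-26.2	-11.40	-10.2	-2.24	-2.4	0.160	0.25
UA	1	0	1	1	0	1	0	-0.2	32.0	10.7	3.26	-0.02	-1.45	-1.1	-20.5	-22.6	-7.69	-8.1	-1.33	-1.5	0.026	0.06
UC	0	1	0	1	1	1	0	1.3	32.0	9.4	3.38	0.07	-1.70	-2.3	-32.5	-35.5	-12.44	-13.3	-2.35	-2.7	0.135	0.18
UG	0	1	1	2	0	1	1	1.0	31.0	9.9	3.09	0.11	-1.46	-1.8	-26.9	-27.8	-10.44	-10.5	-2.11	-2.1	0.039	0.09
UU	0	0	0	2	0	2	0	-0.8	31.0	7.0	3.18	-0.08	-1.27	-0.9	-19.0	-18.4	-6.82	-6.6	-0.93	-1.2	0.160	0.23
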