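tissue	parameter	baseline_median	interim_median	printed_change_pct	formula_consistent
lesions_mean5	suv_mean	6.9	5.7	-17	TRUE
lesions_mean5	suv_max	9.8	9.4	-4	TRUE
lesions_mean5	K1	0.19	0.15	-15	FALSE
lesions_mean5	k3	0.19	0.18	-5	TRUE
lesions_mean5	Ki	0.05	0.03	-40	TRUE
lesions_mean5	FD	1.19	1.21	2	TRUE
lesions_single	suv_mean	11.0	7.7	-30	TRUE
lesions_single	suv_max	15.1	12.7	-16	TRUE
lesions_single	K1	0.27	0.14	-48	TRUE
lesions_single	k3	0.24	0.22	-8	TRUE
lesions_single	Ki	0.08	0.06	-25	TRUE
lesions_single	FD	1.29	1.28	-1	TRUE
thyroid	suv_mean	2.1	2.3	10	TRUE
thyroid	suv_max	2.6	3.0	15	TRUE
thyroid	K1	0.32	0.28	-13	TRUE
thyroid	k3	0.08	0.22	64	FALSE
thyroid	Ki	0.02	0.02	0	TRUE
thyroid	FD	1.06	1.09	3	TRUE
bone_marrow	suv_mean	2.3	2.4	4	TRUE
bone_marrow	suv_max	3.1	3.2	3	TRUE
bone_marrow	K1	0.18	0.13	-28	TRUE
bone_marrow	k3	0.09	0.12	33	TRUE
bone_marrow	Ki	0.03	0.02	-33	TRUE
bone_marrow	FD	1.06	1.07	1	TRUE
spleen	suv_mean	2.3	2.2	-4	TRUE
spleen	suv_max	3.2	3.2	0	TRUE
spleen	K1	0.40	0.25	-38	TRUE
spleen	k3	0.07	0.05	-29	TRUE
spleen	Ki	0.03	0.03	0	TRUE
spleen	FD	1.10	1.09	-1	TRUE
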