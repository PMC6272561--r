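structure	arm	term	mean	std
cyp3a4t	normal	dE_ele	-20.80	2.71
cyp3a4t	cooperative	dE_ele	-25.68	3.08
cyp3a4w	normal	dE_ele	-31.63	3.45
cyp3a4w	cooperative	dE_ele	-25.29	3.57
cyp3a4t	normal	dE_vdw	-65.33	2.46
cyp3a4t	cooperative	dE_vdw	-74.99	2.57
cyp3a4w	normal	dE_vdw	-57.44	2.37
cyp3a4w	cooperative	dE_vdw	-75.63	3.42
cyp3a4t	normal	dE_gas	-86.13	3.34
cyp3a4t	cooperative	dE_gas	-100.67	3.68
cyp3a4w	normal	dE_gas	-89.06	3.17
cyp3a4w	cooperative	dE_gas	-100.92	4.35
cyp3a4t	normal	dG_nonpolar_PB	-8.37	0.21
cyp3a4t	cooperative	dG_nonpolar_PB	-8.44	0.14
cyp3a4w	normal	dG_nonpolar_PB	-7.79	0.06
cyp3a4w	cooperative	dG_nonpolar_PB	-7.84	0.15
cyp3a4t	normal	dG_sol_PB	47.27	3.84
cyp3a4t	cooperative	dG_sol_PB	53.11	3.15
cyp3a4w	normal	dG_sol_PB	59.24	2.46
cyp3a4w	cooperative	dG_sol_PB	56.43	2.67
cyp3a4t	normal	dG_ele_PB	34.84	3.64
cyp3a4t	cooperative	dG_ele_PB	35.87	4.17
cyp3a4w	normal	dG_ele_PB	35.40	4.15
cyp3a4w	cooperative	dG_ele_PB	38.97	3.86
cyp3a4t	normal	dG_bind_PB	-38.86	4.00
cyp3a4t	cooperative	dG_bind_PB	-47.56	4.36
cyp3a4w	normal	dG_bind_PB	-29.83	4.26
cyp3a4w	cooperative	dG_bind_PB	-44.50	4.45
cyp3a4t	normal	dG_nonpolar_GB	-8.37	0.21
cyp3a4t	cooperative	dG_nonpolar_GB	-8.44	0.14
cyp3a4w	normal	dG_nonpolar_GB	-7.79	0.16
cyp3a4w	cooperative	dG_nonpolar_GB	-7.84	0.15
cyp3a4t	normal	dG_sol_GB	31.72	2.50
cyp3a4t	cooperative	dG_sol_GB	33.72	2.21
cyp3a4w	normal	dG_sol_GB	38.10	2.85
cyp3a4w	cooperative	dG_sol_GB	34.11	2.04
cyp3a4t	normal	dG_ele_GB	19.29	2.23
cyp3a4t	cooperative	dG_ele_GB	16.48	2.44
cyp3a4w	normal	dG_ele_GB	14.26	2.44
cyp3a4w	cooperative	dG_ele_GB	16.65	2.82
cyp3a4t	normal	dG_bind_GB	-54.41	2.64
cyp3a4t	cooperative	dG_bind_GB	-66.95	3.12
cyp3a4w	normal	dG_bind_GB	-50.97	3.22
cyp3a4w	cooperative	dG_bind_GB	-66.81	3.74
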