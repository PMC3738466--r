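table	category	cluster	ratio1	ratio2	overlap	p_twins	p_obj
semantic	four_limbed_animals	1	0.73	0.96	0.71	0.0000	0.0000
semantic	faces	4	0.78	1.00	0.78	0.0023	0.0000
semantic	fishes	1	0.75	1.00	0.75	0.0742	0.0007
semantic	sea_invertebrates	5	0.50	0.86	0.46	0.0840	0.0004
semantic	birds	1	1.00	0.48	0.48	0.1048	0.0003
semantic	music_instruments	3	0.50	0.75	0.43	0.1140	0.0012
semantic	vehicles	1	0.46	0.67	0.37	0.2617	0.0065
semantic	insects	3	0.58	0.47	0.35	0.3635	0.0192
semantic	tools	3	0.58	0.44	0.33	0.4587	0.0365
semantic	trees	5	0.30	1.00	0.30	0.6240	0.0979
semantic	buildings	5	0.33	1.00	0.33	0.8883	0.1471
shape_based	round_2	4	1.00	1.00	1.00	0.0000	0.0000
shape_based	star_like_14	5	0.71	0.91	0.67	0.0007	0.0000
shape_based	dim_8	2	0.78	0.78	0.64	0.0097	0.0000
shape_based	vertical_thin_13	3	0.52	0.68	0.42	0.0347	0.0002
shape_based	horiz_thin_6	3	0.41	1.00	0.41	0.0520	0.0003
shape_based	bright_1	2	0.57	0.66	0.44	0.0748	0.0004
shape_based	horiz_thick_5	1	0.44	0.87	0.41	0.0927	0.0008
shape_based	diagonal_12	1	0.47	0.50	0.32	0.4299	0.0392
shape_based	cat_15	1	0.50	0.50	0.33	0.4878	0.0368
shape_based	cat_10	3	0.45	0.50	0.31	0.5313	0.0667
shape_based	cat_11	3	0.31	1.00	0.30	0.5347	0.0582
shape_based	cat_4	1	0.45	0.41	0.28	0.7109	0.1694
shape_based	pointy_7	5	0.27	0.60	0.23	0.9279	0.4949
shape_based	cat_9	1	0.29	0.50	0.22	0.9451	0.5630
shape_based	cat_3	2	0.33	0.40	0.22	0.9530	0.5768
low_level	high_area	4	0.93	1.00	0.93	0.0000	0.0000
low_level	low_contrast	2	0.60	0.82	0.53	0.0103	0.0000
low_level	low_area	3	0.60	0.69	0.47	0.0333	0.0001
low_level	high_luminance	2	0.53	0.80	0.47	0.0352	0.0001
low_level	low_aspect_ratio	2	0.40	0.86	0.37	0.1910	0.0049
low_level	high_aspect_ratio	4	0.33	0.83	0.31	0.4760	0.0454
low_level	low_luminance	1	0.33	0.42	0.28	0.9240	0.5116
low_level	high_contrast	1	0.33	0.36	0.21	0.9761	0.7167
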