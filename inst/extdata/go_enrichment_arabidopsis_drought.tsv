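gene_set	ontology	term	p	q	fold	N	B	n	b
met	BP	response to stimulus	2.52e-13	4.83e-10	1.14	24410	5797	6216	1688
met	BP	response to chemical stimulus	2.52e-12	3.22e-09	1.19	24410	3325	6216	1011
met	BP	response to abiotic stimulus	2.31e-11	1.48e-08	1.23	24410	2269	6216	711
met	BP	response to abscisic acid stimulus	4.43e-07	7.7e-05	1.4	24410	484	6216	172
met	BP	organ development	6.9e-06	0.000644	1.41	24410	363	6216	130
met	BP	drug transmembrane transport	9.11e-06	0.000811	2.03	24410	62	6216	32
met	BP	response to ethylene stimulus	1.04e-05	0.000906	1.44	24410	300	6216	110
met	BP	response to cadmium ion	1.17e-05	0.000995	1.38	24410	393	6216	138
met	BP	response to osmotic stress	2.17e-05	0.00151	1.27	24410	678	6216	220
met	BP	response to stress	4.27e-05	0.00255	1.11	24410	3386	6216	956
met	BP	response to salt stress	5.42e-05	0.003	1.27	24410	638	6216	206
met	BP	organ morphogenesis	0.00011	0.00576	1.38	24410	295	6216	104
met	BP	carbohydrate metabolic process	0.000132	0.00674	1.15	24410	1680	6216	492
met	BP	metal ion transport	0.000186	0.00923	1.28	24410	507	6216	165
met	BP	regulation of anion channel activity	0.000203	0.00934	2.33	24410	27	6216	16
met	BP	auxin polar transport	0.000281	0.0116	1.72	24410	80	6216	35
met	BP	response to red or far red light	0.000306	0.0123	1.33	24410	336	6216	114
met	BP	monocarboxylic acid metabolic process	0.000455	0.0168	1.17	24410	1074	6216	321
met	BP	chloroplast organization	0.000509	0.0185	1.44	24410	186	6216	68
met	BP	protein targeting to membrane	0.000527	0.0189	1.31	24410	354	6216	118
met	BP	cellular nitrogen compound catabolic process	0.000553	0.0196	1.39	24410	226	6216	80
met	BP	response to auxin stimulus	0.000594	0.0207	1.31	24410	355	6216	118
met	BP	cellular protein modification process	0.000602	0.0208	1.12	24410	2090	6216	595
met	BP	auxin homeostasis	0.000738	0.023	2.54	24410	17	6216	11
met	BP	root hair cell differentiation	0.000782	0.0239	1.52	24410	124	6216	48
met	BP	xylem development	0.000842	0.025	1.71	24410	69	6216	30
met	BP	negative regulation of transcription, DNA-dependent	0.000929	0.0265	1.31	24410	321	6216	107
met	BP	regulation of plant-type hypersensitive response	0.000959	0.027	1.3	24410	335	6216	111
met	MF	acid phosphatase activity	1.53e-07	6.87e-05	2.84	24410	29	6216	21
met	MF	transmembrane transporter activity	5.45e-07	0.000153	1.29	24410	873	6216	286
met	MF	secondary active transmembrane transporter activity	1.93e-06	0.000361	1.51	24410	262	6216	101
met	MF	flavin adenine dinucleotide binding	6.93e-06	0.000974	1.66	24410	144	6216	61
met	MF	ATP binding	6.13e-05	0.0053	1.15	24410	1818	6216	533
met	MF	secondary active sulfate transmembrane transporter activity	6.93e-05	0.00576	3.93	24410	7	6216	7
met	MF	heme binding	0.00025	0.0152	1.33	24410	348	6216	118
met	MF	antiporter activity	0.000356	0.0186	1.53	24410	136	6216	53
met	MF	ATPase activity, coupled to transmembrane movement of substances	0.000447	0.0219	1.49	24410	153	6216	58
met	MF	inorganic cation transmembrane transporter activity	0.000583	0.0262	1.37	24410	243	6216	85
met	MF	UDP-N-acetylmuramate dehydrogenase activity	0.000599	0.0264	1.92	24410	45	6216	22
met	MF	water transmembrane transporter activity	0.000842	0.035	2.32	24410	22	6216	13
met	MF	water channel activity	0.000842	0.0357	2.32	24410	22	6216	13
unmet	BP	response to stimulus	1.46e-06	0.00111	1.31	24113	5653	760	234
unmet	BP	raffinose family oligosaccharide biosynthetic process	6.12e-07	0.000579	22.66	24113	7	760	5
unmet	BP	respiratory burst involved in defense response	3.24e-05	0.00945	3.85	24113	107	760	13
unmet	BP	regulation of meristem structural organization	4.85e-05	0.0122	11.33	24113	14	760	5
unmet	BP	negative regulation of gibberellic acid mediated signaling pathway	6.19e-05	0.0138	15.86	24113	8	760	4
unmet	BP	monocarboxylic acid metabolic process	8e-05	0.0159	1.7	24113	1044	760	56
unmet	BP	hyperosmotic salinity response	0.000139	0.0239	3.35	24113	123	760	13
unmet	BP	carboxylic acid biosynthetic process	0.000143	0.0226	1.71	24113	945	760	51
unmet	BP	sesquiterpenoid biosynthetic process	0.000432	0.0496	5.95	24113	32	760	6
unmet	BP	jasmonic acid mediated signaling pathway	0.000556	0.0554	2.41	24113	237	760	18
unmet	BP	response to water deprivation	0.000668	0.0617	2.15	24113	324	760	22
unmet	BP	response to auxin stimulus	0.000682	0.06	2.11	24113	346	760	23
unmet	BP	response to chitin	0.000689	0.0593	2.07	24113	368	760	24
unmet	BP	anatomical structure development	0.000705	0.0593	1.53	24113	1268	760	61
unmet	BP	regulation of defense response	0.000842	0.065	1.92	24113	463	760	28
unmet	BP	regulation of cellular biosynthetic process	0.000922	0.0671	1.37	24113	2249	760	97
unmet	BP	attachment of spindle microtubules to kinetochore	0.000992	0.0671	31.73	24113	2	760	2
unmet	MF	binding	0.000205	0.453	1.16	24113	9528	760	348
unmet	MF	nucleic acid binding transcription factor activity	0.00031	0.344	1.52	24113	1459	760	70
unmet	MF	sequence-specific DNA binding transcription factor activity	0.00031	0.229	1.52	24113	1459	760	70
unmet	MF	catalytic activity	0.000445	0.247	1.18	24113	7647	760	284
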