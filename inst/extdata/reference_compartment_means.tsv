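metabolite	b0_um	p0_um	b0_minus_p0_um	b29_um	p29_um	b29_minus_p29_um
Lactate	3418.6	2378.42	1040.27	3648.98	4067.95	-418.96
Urea	5018.23	4464.38	553.85	8532.33	9175.15	-642.82
Glutamate	459.979	156.271	303.71	205.69	231.334	-25.64
Triacylglyceride	2299.07	2051.74	247.33	1488.55	1527.89	-39.34
Glycine	450.072	354.293	95.78	405.158	388.339	16.82
Glucose	5375.17	6066.73	-691.57	3764.65	4392.07	-627.42
Glycerol	450.072	354.293	-210.14	405.158	388.339	112.27
Cholesterol esters	3352.81	3545.79	-192.99	4085.96	4050.43	35.54
Glutamine	352.78	442.421	-89.64	380.068	372.481	7.59
3-Hydroxybutyrate	147.16	236.31	-89.15	41.72	62.46	-20.74
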