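snp_id	chr	pos	effect_allele	other_allele	weight	p
rs6688363	1	160100000	T	C	1	1.6e-07
rs10170310	2	138800000	G	A	1	1.0e-07
rs7395555	11	30500000	C	G	1	2.0e-07
rs711355	15	29900000	T	C	1	2.3e-07
rs17382202	5	58300000	T	C	1	4.2e-08
rs2980976	18	62300000	A	G	1	3.0e-07
rs1875705	4	93200000	A	G	1	1.1e-08
rs2133450	3	6800000	C	A	1	4.3e-08
rs10023464	4	25400000	T	C	1	9.0e-66
rs7668556	4	150200000	A	T	1	4.0e-13
rs12767583	10	94800000	T	C	1	1.0e-16
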