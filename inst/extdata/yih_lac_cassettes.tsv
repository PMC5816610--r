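cassette_id	gene_id	locus_tag	replicon_id	species	taxon_group	start	end	strand	product	ec_numbers	cog
yih	yihO	b3876	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	1000	2300	+	putative sulfoquinovose permease		
yih	yihP	b3877	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	2400	3750	+	putative galactoside permease		
yih	yihQ	b3878	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	3900	5900	+	alpha-glucosidase	3.2.1.-	
yih	yihR	b3879	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	6000	6900	+	aldose 1-epimerase	5.1.3.3	
yih	yihS	b3880	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	7000	8200	+	sulfoquinovose isomerase	2.3.1.-	
yih	yihT	b3881	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	8300	9200	+	sulfofructosephosphate aldolase	4.1.2.-	COG3684
yih	yihU	b3882	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	9300	10200	+	3-sulfolactaldehyde reductase	1.1.1.-	
yih	yihV	b3883	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	10300	11200	+	sulfofructose kinase	2.7.1.-	
yih	yihW	b3884	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	11300	12100	-	DeoR-family transcriptional regulator		
yih	yihX	b3885	EC_chr	Escherichia coli K-12 MG1655	Enterobacteriaceae	12200	12800	+	alpha-D-glucose 1-phosphate phosphatase	3.1.3.-	
lac	lacR	SA2150	SA_chr	Staphylococcus aureus	Bacilli	100	1100	-	lactose catabolism repressor LacR		
lac	lacA	SA2151	SA_chr	Staphylococcus aureus	Bacilli	1200	1650	+	galactose-6-phosphate isomerase subunit LacA	2.3.1.-	
lac	lacB	SA2152	SA_chr	Staphylococcus aureus	Bacilli	1700	2210	+	galactose-6-phosphate isomerase subunit LacB	2.3.1.-	
lac	lacC	SA2153	SA_chr	Staphylococcus aureus	Bacilli	2300	3230	+	tagatose-6-phosphate kinase	2.7.1.144	
lac	lacD	SA2154	SA_chr	Staphylococcus aureus	Bacilli	3300	4280	+	tagatose 1,6-diphosphate aldolase	4.1.2.40	COG3684
lac	lacE	SA2155	SA_chr	Staphylococcus aureus	Bacilli	4400	6120	+	PTS system lactose-specific transporter subunit IIBC		
lac	lacG	SA2156	SA_chr	Staphylococcus aureus	Bacilli	6200	7600	+	6-phospho-beta-galactosidase	3.2.1.85	
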