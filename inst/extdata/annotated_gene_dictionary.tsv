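locus_tag	symbol	synonyms	product	pathway	go_terms
dde_0527	dsvB	dsrB	Sulfite reductase, dissimilatory-type beta subunit	sulfur metabolism	GO:0006790:P;GO:0009055:F;GO:0018551:F;GO:0020037:F;GO:0046872:F;GO:0051539:F
dde_0526	dsrA	dsvA	Sulfite reductase, dissimilatory-type alpha subunit	sulfur metabolism	GO:0018551:F;GO:0020037:F;GO:0046872:F;GO:0051539:F
dde_3080	cysL		Cysteine synthase A	sulfur metabolism	GO:0004124:F;GO:0006535:P
dde_1110	aprA	apsA	Cysteine synthase A	sulfur metabolism	GO:0016491:F
dde_1109	aprB	apsB	Cysteine synthase A	sulfur metabolism	GO:0046872:F;GO:0051536:F
dde_0762	dsrC		Sulfite reductase, dissimilatory-type gamma subunit	sulfur metabolism	GO:0005737:C;GO:0018551:F
dde_1789	CysH		Phosphoadenosine phosphosulfate reductase	sulfur metabolism	GO:0003824:F
dde_2265	sat		Sulfate adenylyltransferase	sulfur metabolism	GO:0000103:P;GO:0004781:F;GO:0005524:F
dde_3519	modB		Molybdate ABC transporter, inner membrane subunit	transporters	GO:0005886:C;GO:0015098:F;GO:0016021:C
dde_0155	modA		Molybdenum ABC transporter, periplasmic molybdate-binding protein	transporters	GO:0015689:P;GO:0046872:F
dde_3518	modC		Molybdenum ABC transporter, periplasmic molybdate-binding protein	transporters	GO:0015689:P;GO:0030973:F;GO:0046872:F
dde_0717	cyc	fdhA	Formate dehydrogenase, alpha subunit	energy metabolism	GO:0008863:F;GO:0008940:F;GO:0009055:F;GO:0042597:C;GO:0043546:F;GO:0045333:P;GO:0046872:F;GO:0047111:F;GO:0051539:F
dde_0680	dsrM		Cytochrome b/b6 domain-containing protein	energy metabolism	GO:0005886:C;GO:0009055:F;GO:0016021:C;GO:0022904:P
dde_0652	hmcB		Formate dehydrogenase iron-sulfur subunit	energy metabolism	GO:0046872:F;GO:0051536:F
dde_1209	hdrA	qmoA	4Fe-4S ferredoxin iron-sulfur binding domain-containing	energy metabolism	GO:0016491:F;GO:0046872:F;GO:0051536:F
dde_1208	hdrB	qmoB	Heterodisulfide reductase, C subunit	energy metabolism	GO:0051912:F
dde_2066	trx	trxB	Thioredoxin reductase	ribosome synthesis	GO:0004791:F;GO:0005737:C;GO:0019430:P
dde_1448	upp		Uracil phosphoribosyltransferase	nucleotide metabolism	GO:0000287:F;GO:0004845:F;GO:0005525:F;GO:0006223:P;GO:0009116:P;GO:0044206:P
dde_2134	HydA		Hydrogenase (NiFe) small subunit HydA	two-component system	GO:0008901:F;GO:0009375:C;GO:0042597:C;GO:0046872:F;GO:0047806:F;GO:0051538:F;GO:0051539:F
dde_2135	HydB		Periplasmic (NiFeSe) hydrogenase, large subunit, selenocysteine-containing	two-component system	GO:0008901:F;GO:0016151:F;GO:0047806:F
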