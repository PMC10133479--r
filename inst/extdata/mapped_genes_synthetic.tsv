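symbol	locus_tag	product	pathway
dsvB	dde_0527	Sulfite reductase, dissimilatory-type beta subunit	sulfur metabolism
dsrA	dde_0526	Sulfite reductase, dissimilatory-type alpha subunit	sulfur metabolism
cysL	dde_3080	Cysteine synthase A	sulfur metabolism
aprA	dde_1110	Cysteine synthase A	sulfur metabolism
aprB	dde_1109	Cysteine synthase A	sulfur metabolism
dsrC	dde_0762	Sulfite reductase, dissimilatory-type gamma subunit	sulfur metabolism
CysH	dde_1789	Phosphoadenosine phosphosulfate reductase	sulfur metabolism
sat	dde_2265	Sulfate adenylyltransferase	sulfur metabolism
modB	dde_3519	Molybdate ABC transporter, inner membrane subunit	transporters
modA	dde_0155	Molybdenum ABC transporter, periplasmic molybdate-binding protein	transporters
modC	dde_3518	Molybdenum ABC transporter, periplasmic molybdate-binding protein	transporters
cyc	dde_0717	Formate dehydrogenase, alpha subunit	energy metabolism
dsrM	dde_0680	Cytochrome b/b6 domain-containing protein	energy metabolism
hmcB	dde_0652	Formate dehydrogenase iron-sulfur subunit	energy metabolism
hdrA	dde_1209	4Fe-4S ferredoxin iron-sulfur binding domain-containing	energy metabolism
hdrB	dde_1208	Heterodisulfide reductase, C subunit	energy metabolism
trx	dde_2066	Thioredoxin reductase	ribosome synthesis
upp	dde_1448	Uracil phosphoribosyltransferase	nucleotide metabolism
HydA	dde_2134	Hydrogenase (NiFe) small subunit HydA	two-component system
HydB	dde_2135	Periplasmic (NiFeSe) hydrogenase, large subunit, selenocysteine-containing	two-component system
dsrB	dde_0527	Sulfite reductase, dissimilatory-type beta subunit	sulfur metabolism
dsvA	dde_0526	Sulfite reductase, dissimilatory-type alpha subunit	sulfur metabolism
apsA	dde_1110	Cysteine synthase A	sulfur metabolism
apsB	dde_1109	Cysteine synthase A	sulfur metabolism
qmoA	dde_1209	4Fe-4S ferredoxin iron-sulfur binding domain-containing	energy metabolism
qmoB	dde_1208	Heterodisulfide reductase, C subunit	energy metabolism
trxB	dde_2066	Thioredoxin reductase	ribosome synthesis
fdhA	dde_0717	Formate dehydrogenase, alpha subunit	energy metabolism
sat	dde_2265	Sulfate adenylyltransferase	sulfur metabolism
dsrC	dde_0762	Sulfite reductase, dissimilatory-type gamma subunit	sulfur metabolism
modA	dde_0155	Molybdenum ABC transporter, periplasmic molybdate-binding protein	transporters
HydA	dde_2134	Hydrogenase (NiFe) small subunit HydA	two-component system
sat	dde_3137	Sulfate adenylyltransferase	sulfur metabolism
upp	dde_2981	Uracil phosphoribosyltransferase	nucleotide metabolism
trx	dde_1564	Thioredoxin reductase	ribosome synthesis
dsrC	dde_3551	Sulfite reductase, dissimilatory-type gamma subunit	sulfur metabolism
cysH	dde_2951	Phosphoadenosine phosphosulfate reductase	sulfur metabolism
modB	dde_2204	Molybdate ABC transporter, inner membrane subunit	transporters
dsrM	dde_3107	Cytochrome b/b6 domain-containing protein	energy metabolism
hmcB	dde_2649	Formate dehydrogenase iron-sulfur subunit	energy metabolism
cyc	dde_3182	Formate dehydrogenase, alpha subunit	energy metabolism
hydB	dde_0081	Periplasmic (NiFeSe) hydrogenase, large subunit, selenocysteine-containing	two-component system
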