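gene	pathway	partition
dde_0762	sulfur metabolism	persistent
dde_1109	sulfur metabolism	persistent
dde_1110	sulfur metabolism	persistent
dde_0527	sulfur metabolism	persistent
dde_0526	sulfur metabolism	persistent
dde_2271	sulfur metabolism	persistent
dde_3081	sulfur metabolism	persistent
dde_1112	sulfur metabolism	persistent
dde_2115	sulfur metabolism	persistent
dde_2265	sulfur metabolism	persistent
dde_3080	sulfur metabolism	persistent
dde_0528	sulfur metabolism	persistent
dde_1789	sulfur metabolism	shell
sucD	sulfur metabolism	shell
dde_3604	sulfur metabolism	shell
dde_1258	sulfur metabolism	shell
dde_0123	sulfur metabolism	cloud
dde_0276	sulfur metabolism	cloud
rpsM	ribosome synthesis	persistent
rpsE	ribosome synthesis	persistent
rpsD	ribosome synthesis	persistent
fbp	ribosome synthesis	persistent
rpsR	ribosome synthesis	persistent
rpsK	ribosome synthesis	persistent
bamD	ribosome synthesis	persistent
rpmJ	ribosome synthesis	persistent
rplO	ribosome synthesis	persistent
rplQ	ribosome synthesis	persistent
rpmD	ribosome synthesis	persistent
rplS	ribosome synthesis	persistent
rpsP	ribosome synthesis	persistent
rplF	ribosome synthesis	persistent
polA	ribosome synthesis	persistent
rplR	ribosome synthesis	persistent
rpsH	ribosome synthesis	persistent
secY	ribosome synthesis	persistent
tsaD	ribosome synthesis	persistent
rplI	ribosome synthesis	persistent
rpsF	ribosome synthesis	persistent
dde_0002	ribosome synthesis	persistent
dde_2067	ribosome synthesis	persistent
dde_2063	ribosome synthesis	persistent
dde_2225	ribosome synthesis	persistent
dde_1390	ribosome synthesis	persistent
dde_2066	ribosome synthesis	persistent
bamA	ribosome synthesis	shell
dde_0210	ribosome synthesis	shell
dde_2560	ribosome synthesis	shell
dde_2064	ribosome synthesis	cloud
pyrG	nucleotide metabolism	persistent
prs	nucleotide metabolism	persistent
ispH	nucleotide metabolism	persistent
pyrH	nucleotide metabolism	persistent
pyrC	nucleotide metabolism	persistent
aroA	nucleotide metabolism	persistent
pyrF	nucleotide metabolism	persistent
pyrE	nucleotide metabolism	persistent
pyrB	nucleotide metabolism	persistent
glyA	nucleotide metabolism	persistent
ndk	nucleotide metabolism	persistent
frr	nucleotide metabolism	persistent
pcm	nucleotide metabolism	persistent
pyrR	nucleotide metabolism	persistent
tmk	nucleotide metabolism	persistent
upp	nucleotide metabolism	persistent
surE	nucleotide metabolism	persistent
hisC	nucleotide metabolism	persistent
cmk	nucleotide metabolism	persistent
dde_1449	nucleotide metabolism	persistent
dde_2453	nucleotide metabolism	persistent
dde_2112	nucleotide metabolism	persistent
dde_1537	nucleotide metabolism	persistent
dde_2120	nucleotide metabolism	persistent
dde_1569	nucleotide metabolism	persistent
carA	nucleotide metabolism	shell
dde_2631	nucleotide metabolism	shell
tsf	nucleotide metabolism	shell
dde_0140	nucleotide metabolism	cloud
dde_0789	nucleotide metabolism	cloud
moaA	transporters	persistent
moaC	transporters	persistent
dde_3228	transporters	shell
dde_0154	transporters	shell
dde_3518	transporters	shell
dde_0513	transporters	shell
dde_3519	transporters	shell
dde_3520	transporters	shell
dde_0871	transporters	cloud
dde_3517	transporters	cloud
dde_0155	transporters	cloud
dde_1055	transporters	cloud
dde_3513	energy metabolism	persistent
dde_0812	energy metabolism	persistent
dde_1208	energy metabolism	persistent
dde_3514	energy metabolism	persistent
dde_1207	energy metabolism	persistent
dde_0718	energy metabolism	persistent
dde_0652	energy metabolism	persistent
dde_1209	energy metabolism	persistent
dde_0813	energy metabolism	shell
dde_0717	energy metabolism	shell
dde_0706	energy metabolism	shell
dde_1211	energy metabolism	shell
dde_1210	energy metabolism	shell
dde_0680	energy metabolism	shell
dde_3515	energy metabolism	cloud
dde_3756	two-component system	persistent
dde_3237	two-component system	persistent
dde_3755	two-component system	persistent
dde_2138	two-component system	persistent
dde_0364	two-component system	persistent
dde_2139	two-component system	persistent
dde_2137	two-component system	persistent
dde_2135	two-component system	shell
dde_2136	two-component system	shell
dde_2134	two-component system	shell
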