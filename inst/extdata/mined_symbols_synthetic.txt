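dsvB
dsrA
cysL
aprA
aprB
dsrC
CysH
sat
modB
modA
modC
cyc
dsrM
hmcB
hdrA
hdrB
trx
upp
HydA
HydB
nifH
nifD
dnaK
dnaJ
groEL
groES
recA
rpoB
rpoD
gyrA
gyrB
ftsZ
ftsA
lexA
uvrA
sodB
katG
fur
oxyR
arcA
narG
nirK
norB
nosZ
cooS
cooF
hybA
hybB
echA
echB
mcrA
fdoG
fdoH
phsA
psrA
ttrA
dmsA
torA
bisC
cysJ
cysI
metE
metH
serA
glnA
gltB
argH
leuB
thrC
dsrB
dsvA
apsA
apsB
qmoA
qmoB
trxB
fdhA
sat
dsrC
modA
HydA
sat
upp
trx
dsrC
cysH
modB
dsrM
hmcB
cyc
hydB
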