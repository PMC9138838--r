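residue,headgroup,tail1,tail2,db1,db2,leaflet,count
DAPC,PC,DA,DA,4,4,both,160
DUPC,PC,DU,DU,3,3,both,160
PUPC,PC,PU,PU,5,5,both,160
PIPC,PC,PI,PI,2,2,both,160
CHOL,CHOL,,,0,0,both,280
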