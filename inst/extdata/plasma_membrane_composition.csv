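residue,headgroup,tail1,tail2,db1,db2,leaflet,count
DAPE,PE,DA,DA,4,4,inner,440
DAPC,PC,DA,DA,4,4,inner,180
DAPS,PS,DA,DA,4,4,inner,120
DUPE,PE,DU,DU,3,3,inner,280
PUPC,PC,PU,PU,5,5,inner,160
PUPS,PS,PU,PU,5,5,inner,130
POPE,PE,PO,PO,1,1,inner,420
PIPC,PC,PI,PI,2,2,inner,330
DPSM,SM,DP,PN,0,0,inner,250
POPC,PC,PO,PO,1,1,outer,780
PNSM,SM,PN,PN,0,0,outer,330
DPPC,PC,DP,DP,0,0,outer,300
DPGM,GM,DP,DP,0,0,outer,190
DPCE,CER,DP,PN,0,0,outer,140
PUPE,PE,PU,PU,5,5,outer,120
POSM,SM,PO,PN,1,0,outer,250
PODG,DAG,PO,PO,1,1,outer,200
CHOL,CHOL,,,0,0,both,1980
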