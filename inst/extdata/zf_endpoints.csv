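endpoint,hpf,description
MO24,24,mortality at 24 hpf
SM24,24,abnormal spontaneous movement at 24 hpf
MORT,120,mortality at 120 hpf
YSE,120,yolk sac edema
PE,120,pericardial edema
AXIS,120,bent or curved body axis
EYE,120,eye malformation
SNOUT,120,snout malformation
JAW,120,jaw malformation
CFIN,120,caudal fin malformation
PFIN,120,pectoral fin malformation
TRUNK,120,truncated trunk or tail
SWIM,120,uninflated swim bladder
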