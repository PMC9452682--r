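alteration_id,node,status
ATM_act,ATM,A
p53_act,p53,A
WIP1_act,WIP1,A
MDM2_act,MDM2,A
MDMX_act,MDMX,A
CYCG_act,CYCG,A
PTEN_act,PTEN,A
AKT_act,AKT,A
CYCE_act,CYCE,A
RB_act,RB,A
E2F1_act,E2F1,A
ARF_act,ARF,A
BCL2_act,BCL2,A
BAX_act,BAX,A
ATM_inact,ATM,I
p53_inact,p53,I
WIP1_inact,WIP1,I
MDM2_inact,MDM2,I
MDMX_inact,MDMX,I
CYCG_inact,CYCG,I
PTEN_inact,PTEN,I
AKT_inact,AKT,I
CYCE_inact,CYCE,I
RB_inact,RB,I
E2F1_inact,E2F1,I
ARF_inact,ARF,I
BCL2_inact,BCL2,I
BAX_inact,BAX,I
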