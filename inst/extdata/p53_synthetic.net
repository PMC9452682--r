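# Synthetic 16-node p53-signaling model (NOT a transcription of any published
# parameter set: node names, link structure and the 6-target screening
# combinatorics follow the p53 literature; weights and basal levels are
# package-chosen minimal integers).
# Drug-target nodes: AKT BCL2 CYCE MDM2 WIP1 ATM (27 outgoing links).
[nodes]
name	basal	role
DNA_damage	0	input
ATM	0	internal
p53	0	internal
WIP1	0	internal
MDM2	0	internal
MDMX	1	internal
CYCG	0	internal
PTEN	0	internal
AKT	1	internal
CYCE	0	internal
RB	1	internal
E2F1	1	internal
ARF	0	internal
BCL2	0	internal
BAX	0	internal
CASP3	0	output
[links]
source	target	weight
DNA_damage	ATM	2
ATM	p53	3
ATM	MDM2	-1
ATM	MDMX	-1
ATM	E2F1	1
ATM	AKT	-1
ATM	BCL2	-1
p53	MDM2	1
p53	WIP1	1
p53	CYCG	1
p53	PTEN	1
p53	BAX	2
p53	BCL2	-1
WIP1	p53	-1
WIP1	ATM	-1
WIP1	ARF	-1
WIP1	MDM2	1
MDM2	p53	-2
MDM2	MDMX	-1
MDM2	RB	-1
MDM2	E2F1	1
MDM2	ARF	-1
MDM2	ATM	-1
MDM2	BAX	-1
MDMX	p53	-1
CYCG	MDM2	1
PTEN	AKT	-2
AKT	MDM2	1
AKT	MDMX	1
AKT	BAX	-1
AKT	BCL2	1
CYCE	RB	-1
CYCE	E2F1	1
CYCE	p53	-1
RB	E2F1	-2
E2F1	CYCE	1
E2F1	ARF	1
ARF	MDM2	-2
BCL2	BAX	-2
BCL2	CASP3	-2
BCL2	AKT	1
BAX	CASP3	2
[metadata]
death_readout	CASP3
version	p53-synthetic-1
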