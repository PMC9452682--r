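# minimal three-node teaching model: X drives the death readout Z, Y represses it
[nodes]
name	basal	role
X	1	internal
Y	0	internal
Z	0	output
[links]
source	target	weight
X	Z	1
Y	Z	-1
[metadata]
death_readout	Z
version	toy-1
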