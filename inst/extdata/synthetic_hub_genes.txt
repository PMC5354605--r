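hgene001
hgene002
hgene003
hgene004
hgene005
hgene006
sgene001
sgene005
sgene007
sgene013
sgene022
sgene023
sgene025
sgene029
sgene034
sgene037
sgene038
sgene044
sgene046
sgene051
sgene052
sgene061
sgene063
sgene067
sgene068
sgene069
sgene070
sgene071
sgene075
sgene083
sgene086
sgene091
sgene097
sgene103
sgene108
sgene110
sgene113
sgene115
sgene117
sgene121
sgene125
sgene126
sgene128
sgene130
sgene131
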