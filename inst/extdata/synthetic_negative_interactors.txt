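sgene001
sgene002
sgene003
sgene004
sgene005
sgene006
sgene007
sgene008
sgene009
sgene010
sgene011
sgene012
sgene013
sgene014
sgene015
sgene016
sgene017
sgene018
sgene019
sgene020
sgene021
sgene022
sgene023
sgene024
sgene025
sgene026
sgene027
sgene028
sgene029
sgene030
sgene031
sgene032
sgene033
sgene034
sgene035
sgene036
sgene037
sgene038
sgene039
sgene040
sgene041
sgene042
sgene043
sgene044
sgene045
sgene046
sgene047
sgene048
sgene049
sgene050
sgene051
sgene052
sgene053
sgene054
sgene055
sgene056
sgene057
sgene058
sgene059
sgene060
sgene061
sgene062
sgene063
sgene064
sgene065
sgene066
sgene067
sgene068
sgene069
sgene070
sgene071
sgene072
sgene073
sgene074
sgene075
sgene076
sgene077
sgene078
sgene079
sgene080
sgene081
sgene082
sgene083
sgene084
sgene085
sgene086
sgene087
sgene088
sgene089
sgene090
sgene091
sgene092
sgene093
sgene094
sgene095
sgene096
sgene097
sgene098
sgene099
sgene100
sgene101
sgene102
sgene103
sgene104
sgene105
sgene106
sgene107
sgene108
sgene109
sgene110
sgene111
sgene112
sgene113
sgene114
sgene115
sgene116
sgene117
sgene118
sgene119
sgene120
sgene121
sgene122
sgene123
sgene124
sgene125
sgene126
sgene127
sgene128
sgene129
sgene130
sgene131
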