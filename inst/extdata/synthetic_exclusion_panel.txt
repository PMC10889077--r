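g0101
g0102
g0103
g0104
g0105
g0106
g0107
g0108
g0109
g0110
g0111
g0112
g0113
g0114
g0115
g0116
g0117
g0118
g0119
g0120
g0121
g0122
g0123
g0124
g0125
g0126
g0127
g0128
g0129
g0130
g0131
g0132
g0133
g0134
g0135
g0136
g0137
g0138
g0139
g0140
g0141
g0142
g0143
g0144
g0145
g0146
g0147
g0148
g0149
g0150
g0151
g0152
g0153
g0154
g0155
g0156
g0157
g0158
g0159
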