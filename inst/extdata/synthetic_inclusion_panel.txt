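g0001
g0002
g0003
g0004
g0005
g0006
g0007
g0008
g0009
g0010
g0011
g0012
g0013
g0014
g0015
g0016
g0017
g0018
g0019
g0020
g0021
g0022
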