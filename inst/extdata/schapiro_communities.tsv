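vertex	community
v01	1
v02	1
v03	1
v04	1
v05	1
v06	2
v07	2
v08	2
v09	2
v10	2
v11	3
v12	3
v13	3
v14	3
v15	3
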