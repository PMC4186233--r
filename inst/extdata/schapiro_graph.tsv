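from	to
v01	v02
v01	v03
v01	v04
v02	v03
v02	v04
v02	v05
v03	v04
v03	v05
v04	v05
v06	v07
v06	v08
v06	v09
v07	v08
v07	v09
v07	v10
v08	v09
v08	v10
v09	v10
v11	v12
v11	v13
v11	v14
v12	v13
v12	v14
v12	v15
v13	v14
v13	v15
v14	v15
v05	v06
v10	v11
v15	v01
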