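road,type,length,flow,accidents,victims,fatalities
Cuernavaca Federal,federal,60.5,467.9,105,159,22
Cuernavaca Toll,toll,70.7,1204.7,106,128,23
Toluca Federal,federal,55,764.5,117,90,20
Toluca Toll,toll,55,1589.4,46,45,15
Pachuca Federal,federal,62.5,1761.3,162,161,29
Pachuca Toll,toll,62.5,1083.3,62,99,20
Puebla Federal,federal,121,2736.3,49,63,13
Puebla Toll,toll,121,2725.7,162,309,46
Queretaro Toll,toll,164,1548.8,293,362,64
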