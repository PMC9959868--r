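class,level,correct,total
homogeneous,positive,722,815
speckled,positive,900,1092
nucleolar,positive,450,500
centromere,positive,955,1033
nuclear_membrane,positive,655,707
golgi,positive,300,366
homogeneous,intermediate,902,1055
speckled,intermediate,900,1030
nucleolar,intermediate,1000,1248
centromere,intermediate,950,1022
nuclear_membrane,intermediate,810,948
golgi,intermediate,200,280
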