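compound,ot_ug_per_l
Dimethyl sulfide,0.3
beta-Ionone,0.021
Linalool,0.6
(Z)-Jasmone,0.26
alpha-Pinene,5.3
Geraniol,3.2
3-Methyl butanal,0.5
2-Methyl butanal,1.5
Hexanal,2.4
Heptanal,6.1
"(E,E)-3,5-Octadien-2-one",0.5
alpha-Terpineol,4.08
Indole,11
alpha-Ionone,0.3
Decanal,0.1
Nonanal,2.8
beta-Cyclocitral,3
(Z)-3-Hexen-1-ol,2
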