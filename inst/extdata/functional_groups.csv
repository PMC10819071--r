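name,pattern
hydroxyl,O[H]
amino,N([H])[H]
methyl,C([H])([H])[H]
carboxyl,C(=O)O[H]
carbonyl,C=O
nitro,N(~[OD1])~[OD1]
ester,C(=O)OC
amide,C(=O)N
ether,COC
thiol,S[H]
halogen,"[F,Cl,Br,I]"
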