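# Mammalian cell-cycle Boolean network, 10 genes.
# Transcribed from the logical model of Faure, Naldi, Chaouiya & Thieffry
# (2006), "Dynamical analysis of a generic Boolean model for the control of
# the mammalian cell cycle", Bioinformatics 22(14):e124-e131 (synchronous
# updating). CycD is the extracellular growth-factor input and copies
# itself, so the synchronous system on 2^10 states has exactly two
# attractors: a quiescent fixed point (CycD off; Rb, p27, Cdh1 on) and a
# 7-state oscillatory cycle (CycD on).
CycD = CycD
Rb = (NOT CycD AND NOT CycE AND NOT CycA AND NOT CycB) OR (p27 AND NOT CycD AND NOT CycB)
E2F = (NOT Rb AND NOT CycA AND NOT CycB) OR (p27 AND NOT Rb AND NOT CycB)
CycE = E2F AND NOT Rb
CycA = (E2F AND NOT Rb AND NOT Cdc20 AND NOT (Cdh1 AND UbcH10)) OR (CycA AND NOT Rb AND NOT Cdc20 AND NOT (Cdh1 AND UbcH10))
p27 = (NOT CycD AND NOT CycE AND NOT CycA AND NOT CycB) OR (p27 AND NOT (CycE AND CycA) AND NOT CycB AND NOT CycD)
Cdc20 = CycB
Cdh1 = (NOT CycA AND NOT CycB) OR Cdc20 OR (p27 AND NOT CycB)
UbcH10 = NOT Cdh1 OR (Cdh1 AND UbcH10 AND (Cdc20 OR CycA OR CycB))
CycB = NOT Cdc20 AND NOT Cdh1
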