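# De novo D-serine synthesis pathway, targeted-panel coordinates:
# 3-phosphoglycerate -> 3-phosphohydroxypyruvate -> phosphoserine ->
# L-serine -> D-serine, with the NAD/NADH and Glu/KGA cofactor pairs.
cofactors: NAD, NADH
PHGDH : 3PG + NAD -> 3PHP + NADH
PSAT1 : 3PHP + Glu -> PSer + KGA
PSPH : PSer -> LSer
SRR : LSer -> DSer
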