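# Stage-II pedigree with a more modest family history (LINKAGE
# pre-makeped; reconstruction calibrated to the published index carrier
# probabilities). Columns: fam id father mother sex affection analyzed
# The index case (id 8) is screened; affected: 8, sister 9, aunt 6.
2 1 0 0 1 1 0
2 2 0 0 2 1 0
2 3 0 0 1 0 0
2 4 1 2 2 1 0
2 5 1 2 2 1 0
2 6 1 2 2 2 0
2 7 0 0 1 1 0
2 8 3 4 1 2 1
2 9 3 4 2 2 0
2 10 7 6 1 1 0
2 11 7 6 2 1 0
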