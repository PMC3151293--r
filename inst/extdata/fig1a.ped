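# Stage-I high-risk pedigree (LINKAGE pre-makeped; reconstruction
# calibrated to the published carrier/sharing probabilities).
# Columns: fam id father mother sex affection sequenced
# Affection: 1 unaffected, 2 affected, 0 unknown.
# Sequenced members: 8 (proband), 11 (first cousin), 5 (their aunt).
1 1 0 0 1 1 0
1 2 0 0 2 0 0
1 3 0 0 1 1 0
1 4 1 2 2 1 0
1 5 1 2 2 2 1
1 6 1 2 2 1 0
1 7 0 0 1 1 0
1 8 3 4 1 2 1
1 9 3 4 2 0 0
1 10 7 6 1 1 0
1 11 7 6 2 2 1
1 12 0 0 1 1 0
1 13 12 9 1 2 0
1 14 0 0 1 0 0
1 15 14 5 2 1 0
1 16 14 5 2 1 0
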