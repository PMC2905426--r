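# PARTIAL, RECONSTRUCTED homology map: human (HSA) probes on
# Chiropotes utahicki (CUT). No full homology table is printed for CUT;
# this file covers only the association-bearing chromosomes, reconstructed
# from the published cross-taxon chromosome-form correspondences and the
# comparative discussion (20/15/14 tandem fusion on CUT 1; inverted
# 16a/10a/16a/10a on CUT 7; 3a/21 on CUT 22; retained 2b/16b, 5/7a and
# 8a/18 associations; 7b homologue on CUT 6). Chromosome ids without a
# published correspondence are placeholders. Not a transcription of a
# printed table; do not treat as observed data.
#%probe_species: HSA
#%target_species: CUT
#%probe_chromosomes: 1-22,X,Y
#%diploid_female: 54
#%diploid_male: 54
#%sex_system: XY
probe_chrom	targets
HSA2	10:q
HSA3	22:proximal q
HSA5	11:proximal q
HSA7	11:distal q;6
HSA8	8:p
HSA10	7:proximal p- distal q
HSA14	1:distal q
HSA15	1:q
HSA16	10:p;7:distal p- proximal q
HSA18	8:q
HSA20	1:proximal q
HSA21	22:distal q
HSAX	X
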