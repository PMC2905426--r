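# Cross-species chromosome painting homology map:
# human (HSA) whole-chromosome probes on Cacajao calvus rubicundus (CCR).
# CCR carries a Y-autosome translocation (X1X2Y multiple sex system,
# 2n = 45 male / 46 female): the HSA11 homologue sits on the composite Y;
# X2 is the original homologue of the translocated autosome.
#%probe_species: HSA
#%target_species: CCR
#%probe_chromosomes: 1-22,X,Y
#%extra_chromosomes: X2
#%diploid_female: 46
#%diploid_male: 45
#%sex_system: X1X2Y
probe_chrom	targets
HSA1	11;17;6:p
HSA2	5:q;7:q
HSA3	19:proximal q;2:p;1:distal p
HSA4	9
HSA5	21:proximal q;2:q
HSA6	8
HSA7	21:distal q;10
HSA8	3:p;12
HSA9	14
HSA10	4:proximal p- distal q;7:p
HSA11	Y
HSA12	6:q
HSA13	13
HSA14	1:distal q
HSA15	1:proximal q;18
HSA16	4:distal p- proximal q;5:p
HSA17	16
HSA18	3:q
HSA19	15
HSA20	1:proximal p
HSA21	19:distal q
HSA22	20
HSAX	X
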