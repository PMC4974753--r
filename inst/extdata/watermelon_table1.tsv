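# Published genome-survey tallies for the watermelon 97103 draft assembly:
# per-class SSR locus counts and the number of loci with designable primers.
class_name	n_loci	n_primer_designed
di	13474	11353
tri	8947	7718
tetra	5465	4552
penta	4205	3681
hexa	2082	1938
hepta	4059	3412
octo	1291	1156
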