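# Published marker counts from the watermelon SSR survey, used as inputs to
# the summary arithmetic: markers screened by electronic PCR, single- and
# multi-product markers per target genome, polymorphism screen and the
# germplasm fingerprinting panel.
name	value
markers_epcr_tested	32869
cucumber_single_product	832
cucumber_multi_product	59
cucumber_chromosomes	7
melon_single_product	925
melon_multi_product	44
melon_anchored_single_product	862
melon_chromosomes	12
polymorphism_screen_markers	192
polymorphic_markers	91
panel_markers	32
panel_total_alleles	151
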