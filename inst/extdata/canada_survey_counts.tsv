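quantity	value
total_bins	46937
diptera_tree_representatives	23591
other_orders_tree_representatives	23346
cecidomyiidae_bins	8467
canada_species_estimate	94000
canada_global_fraction	0.01
cecidomyiidae_canada_estimate	20000
diptera_bin_sp	3.34
hymenoptera_bin_sp	2.05
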