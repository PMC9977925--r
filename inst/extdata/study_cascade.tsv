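quantity	value
total_ccgg_sites	1613446
unique_5hmc_across_samples	1096820
after_first_filter	405605
after_second_filter	138000
ymax	19
dhmc_total	2677
dhmc_higher_in_large	2237
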