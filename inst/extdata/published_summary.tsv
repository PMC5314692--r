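# Other printed headline quantities from the same release comparison.
#quantity	value
medium_and_above_v1	142523
medium_and_above_v2	640748
biogrid_negative_share_pct	20.14
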