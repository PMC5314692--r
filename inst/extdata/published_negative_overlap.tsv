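# Printed overlap counts between PPI databases and the manual-stringent
# section of a curated negative (non-interacting) pair reference of size
# 1991. db_size is the printed interaction count of each database.
#db	overlap	db_size	negative_set_size
integrated_v2	871	2922202	1991
integrated_v1	309	604741	1991
string	894	2166793	1991
biogrid	401	219178	1991
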