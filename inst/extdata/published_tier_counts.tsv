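# Star-tier interaction counts printed in the release comparison of a large
# integrated human interactome (previous release v1 vs current release v2),
# with the printed integer-percent increase ratio per tier.
#tier	v1	v2	printed_increase_pct
all	604741	2922202	483
5	37754	175476	464
4	33733	167123	495
3	71036	298149	419
2	189150	854189	452
1	273068	1427265	523
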