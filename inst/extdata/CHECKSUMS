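# md5 checksums of packaged data files
file	md5
table1.tsv	1f8a8724101eb733a7625c17d98e3028
reference_tree.nwk	99523353bc6e4b835f1e4160f7cf9fd3
reference_tip_states.tsv	3033ab55d13e035d0074788c7dfc1819
lambda_rules.tsv	1813862ec3f0df069a1bdf976a26e1b9
overrides.tsv	6643373cfa86eb2592067578d2454697
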