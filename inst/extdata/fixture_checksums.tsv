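file	md5
gene_pool_inventory.tsv	264f573be2f714db740c6effb030943b
range_change_published.tsv	8f70ed07f85a8822084544ac1a12d2d9
priority_published.tsv	3d101c77e006bbf683a191eaf5beca7e
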