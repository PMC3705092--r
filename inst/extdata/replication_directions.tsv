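snp_id	gene	coded_allele	direction
rs12574703	HSPA8	A	+-+-++++-
rs7797781	HSPB1	T	--+-+++++
rs1416733	HSF2	A	-----+---
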