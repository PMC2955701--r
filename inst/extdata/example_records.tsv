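mirna_id	utr_id	site_seq
mir01	mir01_pos001	ACCUGUUA
mir01	mir01_pos001	ACCUGUUA
mir01	mir01_pos001	ACCUGUUU
mir01	mir01_pos002	UUUUGUUA
mir01	mir01_pos003	ACCUGUUA
mir01	mir01_pos003	GACGGUUA
mir01	mir01_pos003	GUUUGUUU
mir02	mir02_pos001	GGGAAAGA
mir02	mir02_pos002	GAGACAAGC
mir02	mir02_pos002	GAGAAAGA
mir02	mir02_pos003	GAGAAAGC
mir02	mir02_pos003	GGGAAAGU
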