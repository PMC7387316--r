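gene_symbol	class
CLOCKA	core
CLOCKB	core
CYCLEC	core
LIGHTIN1	immediate
LIGHTIN2	immediate
LIGHTOUT1	immediate
LIGHTOUT2	immediate
RHYTHM1	distant
RHYTHM2	distant
RHYTHM3	distant
RHYTHM4	distant
RHYTHM5	distant
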