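precursor_id	mirna	start	end
hsa-mir-455_synthetic	miR-455-5p	6	27
hsa-mir-455_synthetic	miR-455-3p	45	65
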