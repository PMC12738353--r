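>hsa-mir-455_synthetic synthetic hairpin context around the genuine mature miR-455-5p arm (positions 6-27; the +1 base at 28 is U); flanks and 3p arm are synthetic, this is NOT the miRBase MI0003513 record
GUGUUUAUGUGCCUUUGGACUACAUCGUGGAAGCCAGCACCAUGGCAGUCCAUGGGCAUAUACACCUU
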