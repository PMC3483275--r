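scheme	codon
brown_synthetic	7
brown_synthetic	9
brown_synthetic	10
brown_synthetic	12
brown_synthetic	14
brown_synthetic	25
brown_synthetic	27
brown_synthetic	29
brown_synthetic	31
brown_synthetic	36
brown_synthetic	37
brown_synthetic	46
brown_synthetic	49
brown_synthetic	50
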