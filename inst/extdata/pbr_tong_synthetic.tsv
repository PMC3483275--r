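scheme	codon
tong_synthetic	7
tong_synthetic	9
tong_synthetic	12
tong_synthetic	13
tong_synthetic	25
tong_synthetic	28
tong_synthetic	29
tong_synthetic	31
tong_synthetic	36
tong_synthetic	38
tong_synthetic	44
tong_synthetic	46
tong_synthetic	50
tong_synthetic	51
tong_synthetic	52
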