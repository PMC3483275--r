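population	allele
Inaccessible	Neso01
Inaccessible	Neso02
Inaccessible	Neso03
Inaccessible	Neso04
Inaccessible	Neso05
Inaccessible	Neso06
Inaccessible	Neso07
Inaccessible	Neso08
Inaccessible	Neso10
Inaccessible	Neso11
Inaccessible	Neso12
Inaccessible	Neso13
Inaccessible	Neso15
Inaccessible	Neso16
Inaccessible	Neso17
Inaccessible	Neso18
Inaccessible	Neso19
Inaccessible	Neso20
Inaccessible	Neso21
Inaccessible	Neso22
Inaccessible	Neso23
Nightingale	Neso01
Nightingale	Neso03
Nightingale	Neso04
Nightingale	Neso07
Nightingale	Neso09
Nightingale	Neso11
Nightingale	Neso13
Nightingale	Neso14
Nightingale	Neso15
Nightingale	Neso17
Nightingale	Neso18
Nightingale	Neso20
Nightingale	Neso22
Nightingale	Neso23
Gough	Neso05
Gough	Neso09
Gough	Neso13
Gough	Neso14
Gough	Neso15
Gough	Neso17
Gough	Neso23
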