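class	Ginermis	Oacuminata	Paurea	Lpauciflora
A	2	2	3	3
B	3	4	3	7
C/D	2	4	5	3
E	3	5	4	3
SOC-like	2	3	4	3
SVP-like	1	1	1	1
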