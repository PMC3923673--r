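c1	10	A	5	..,,.	IIIII
c1	11	A	6	.,TTt.	IIIIII
c1	12	G	3	^I.,,	III
c1	13	T	5	.,*,.	IIIII
c1	14	C	5	.+2AG.,-3ACG,.	IIIII
c2	1	A	5	,,...	IIIII
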