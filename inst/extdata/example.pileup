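chr1	101	A	3	..G	III	2	..	II	3	,,,	III	2	..	II
chr1	150	C	2	.,	II	3	..T	III	2	,,	II	1	.	I
chr1	207	G	4	....	IIII	2	,a	II	3	...	III	2	..	II
chr1	333	T	2	..	II	2	cc	II	2	..	II	3	,,.	III
chr1	410	A	3	.^].	III	2	.$.	II	2	..	II	2	,,	II
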