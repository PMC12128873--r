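chrom	start	end	arm
1	1	50000000	p
1	50000001	120000000	q
2	1	40000000	p
2	40000001	100000000	q
3	1	30000000	p
3	30000001	90000000	q
4	1	25000000	p
4	25000001	70000000	q
5	1	20000000	p
5	20000001	60000000	q
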