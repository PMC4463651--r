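sn	length	region	in_intron_stop	ptc_class
1	37	CDS	FALSE	upstream_far
2	41	CDS	FALSE	downstream_of_last_junction
3	43	CDS	FALSE	upstream_far
4	47	CDS	FALSE	upstream_far
5	49	CDS	FALSE	downstream_of_last_junction
6	50	CDS	FALSE	upstream_far
7	54	CDS	FALSE	no_ptc
8	54	CDS	TRUE	upstream_far
9	55	CDS	FALSE	upstream_far
10	56	CDS	FALSE	upstream_far
11	61	UTR5	FALSE	no_ptc
12	62	CDS	FALSE	upstream_far
13	62	CDS	FALSE	upstream_far
14	62	CDS	FALSE	upstream_far
15	63	CDS	FALSE	no_ptc
16	63	UTR5	FALSE	no_ptc
17	65	CDS	FALSE	upstream_far
18	65	CDS	FALSE	upstream_far
19	65	CDS	FALSE	upstream_far
20	65	CDS	FALSE	upstream_far
21	65	CDS	FALSE	no_ptc
22	65	CDS	FALSE	upstream_far
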