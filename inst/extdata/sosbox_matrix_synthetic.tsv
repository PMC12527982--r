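# Synthetic LexA SOS-box position count matrix (default scoring matrix).
# Constructed around the canonical E. coli operator TACTG(TA)5CAGTA and
# palindromically symmetrized: counts[i][b] == counts[L+1-i][complement(b)].
# It is a stand-in built for this package, not a published site alignment;
# replace with your own matrix (same format) for organism-specific work.
#length=20
#pseudocount=0.5
#n_sites=50
#core=3-5:CTG,16-18:CAG
pos	A	C	G	T
1	10	6	4	30
2	36	4	2	8
3	0	50	0	0
4	0	0	0	50
5	0	0	50	0
6	8	4	4	34
7	28	6	4	12
8	14	6	4	26
9	24	6	4	16
10	18	6	4	22
11	22	4	6	18
12	16	4	6	24
13	26	4	6	14
14	12	4	6	28
15	34	4	4	8
16	0	50	0	0
17	50	0	0	0
18	0	0	50	0
19	8	2	4	36
20	30	4	6	10
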