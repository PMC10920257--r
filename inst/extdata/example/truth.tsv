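position	key	aa	is_epitope	is_core
1	A:1	T	FALSE	FALSE
2	A:2	C	TRUE	FALSE
3	A:3	A	TRUE	FALSE
4	A:4	I	TRUE	FALSE
5	A:5	D	TRUE	FALSE
6	A:6	W	TRUE	FALSE
7	A:7	T	TRUE	FALSE
8	A:8	P	TRUE	FALSE
9	A:9	E	FALSE	FALSE
10	A:10	D	FALSE	FALSE
11	A:11	C	FALSE	FALSE
12	A:12	F	FALSE	FALSE
13	A:13	V	FALSE	FALSE
14	A:14	W	FALSE	TRUE
15	A:15	P	FALSE	FALSE
16	A:16	N	FALSE	FALSE
17	A:17	H	FALSE	FALSE
18	A:18	D	FALSE	FALSE
19	A:19	C	FALSE	FALSE
20	A:20	M	FALSE	FALSE
21	A:21	C	FALSE	FALSE
22	A:22	V	FALSE	FALSE
23	A:23	R	FALSE	FALSE
24	A:24	G	FALSE	FALSE
25	A:25	N	FALSE	FALSE
26	A:26	A	FALSE	FALSE
27	A:27	I	FALSE	FALSE
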