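id	name	hemisphere
1	Precentral gyrus	left
2	Precentral gyrus	right
3	Superior frontal gyrus, dorsolateral	left
4	Superior frontal gyrus, dorsolateral	right
5	Superior frontal gyrus, orbital part	left
6	Superior frontal gyrus, orbital part	right
7	Middle frontal gyrus	left
8	Middle frontal gyrus	right
9	Middle frontal gyrus, orbital part	left
10	Middle frontal gyrus, orbital part	right
11	Inferior frontal gyrus, opercular part	left
12	Inferior frontal gyrus, opercular part	right
13	Inferior frontal gyrus, triangular part	left
14	Inferior frontal gyrus, triangular part	right
15	Inferior frontal gyrus, orbital part	left
16	Inferior frontal gyrus, orbital part	right
17	Rolandic operculum	left
18	Rolandic operculum	right
19	Supplementary motor area	left
20	Supplementary motor area	right
21	Olfactory cortex	left
22	Olfactory cortex	right
23	Superior frontal gyrus, medial	left
24	Superior frontal gyrus, medial	right
25	Superior frontal gyrus, medial orbital	left
26	Superior frontal gyrus, medial orbital	right
27	Gyrus rectus	left
28	Gyrus rectus	right
29	Insula	left
30	Insula	right
31	Anterior cingulate and paracingulate gyri	left
32	Anterior cingulate and paracingulate gyri	right
33	Median cingulate and paracingulate gyri	left
34	Median cingulate and paracingulate gyri	right
35	Posterior cingulate gyrus	left
36	Posterior cingulate gyrus	right
37	Hippocampus	left
38	Hippocampus	right
39	Parahippocampal gyrus	left
40	Parahippocampal gyrus	right
41	Amygdala	left
42	Amygdala	right
43	Calcarine fissure and surrounding cortex	left
44	Calcarine fissure and surrounding cortex	right
45	Cuneus	left
46	Cuneus	right
47	Lingual gyrus	left
48	Lingual gyrus	right
49	Superior occipital gyrus	left
50	Superior occipital gyrus	right
51	Middle occipital gyrus	left
52	Middle occipital gyrus	right
53	Inferior occipital gyrus	left
54	Inferior occipital gyrus	right
55	Fusiform gyrus	left
56	Fusiform gyrus	right
57	Postcentral gyrus	left
58	Postcentral gyrus	right
59	Superior parietal gyrus	left
60	Superior parietal gyrus	right
61	Inferior parietal, but supramarginal and angular gyri	left
62	Inferior parietal, but supramarginal and angular gyri	right
63	Supramarginal gyrus	left
64	Supramarginal gyrus	right
65	Angular gyrus	left
66	Angular gyrus	right
67	Precuneus	left
68	Precuneus	right
69	Paracentral lobule	left
70	Paracentral lobule	right
71	Caudate nucleus	left
72	Caudate nucleus	right
73	Lenticular nucleus, putamen	left
74	Lenticular nucleus, putamen	right
75	Lenticular nucleus, pallidum	left
76	Lenticular nucleus, pallidum	right
77	Thalamus	left
78	Thalamus	right
79	Heschl gyrus	left
80	Heschl gyrus	right
81	Superior temporal gyrus	left
82	Superior temporal gyrus	right
83	Temporal pole: superior temporal gyrus	left
84	Temporal pole: superior temporal gyrus	right
85	Middle temporal gyrus	left
86	Middle temporal gyrus	right
87	Temporal pole: middle temporal gyrus	left
88	Temporal pole: middle temporal gyrus	right
89	Inferior temporal gyrus	left
90	Inferior temporal gyrus	right
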