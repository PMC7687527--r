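trnadb_pos	n_match
13	32
14	44
22	29
23	41
39	40
42	33
43	34
45	11
46	43
54	18
56	10
61	21
63	35
69	39
71	31
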