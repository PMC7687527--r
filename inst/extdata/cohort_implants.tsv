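label	position	ref	alt	vtype	case_carriers	control_carriers
m.15927G>A	15927	G	A	substitution	8	0
m.15951A>G	15951	A	G	substitution	4	0
m.15900T>C	15900	T	C	substitution	1	1
m.15901A>G	15901	A	G	substitution	1	0
m.15908T>C	15908	T	C	substitution	1	1
m.15924A>G	15924	A	G	substitution	9	3
m.15928G>A	15928	G	A	substitution	3	2
m.15931A>C	15931	A	C	substitution	1	0
m.15940DelT	15940	T	Del	deletion	1	0
m.15943T>C	15943	T	C	substitution	2	1
m.15949G>A	15949	G	A	substitution	1	0
m.15907A>G	15907	A	G	substitution	1	0
m.15930G>A	15930	G	A	substitution	2	13
m.15938C>T	15938	C	T	substitution	1	0
m.15941T>C	15941	T	C	substitution	5	2
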