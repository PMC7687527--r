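# Curated minimal mtDNA haplogroup tree (synthetic stand-in for a full
# phylogeny). Each node lists the variants, relative to rCRS, that define
# the branch leading to it; a lineage carries the union of defining
# variants on its root-to-node path. Defining variants were curated from
# East-Asian haplogroup-diagnostic markers; back-mutations are not
# modeled. The file format accepts larger user-supplied trees.
node	parent	defining_variants
rCRS
N	rCRS	m.73A>G;m.263A>G;m.750A>G;m.1438A>G;m.2706A>G;m.4769A>G;m.7028C>T;m.8860A>G;m.11719G>A;m.14766C>T;m.15326A>G
A	N	m.235A>G;m.663A>G;m.1736A>G;m.4824A>G;m.16290C>T;m.16319G>A
B	N	m.8281_8289del
B4	B	m.16217T>C
F	N	m.249DelA;m.6392T>C;m.10310G>A;m.16304T>C
F1a'c	F	m.3970C>T;m.16172T>C
F1a1	F1a'c	m.4086C>T;m.16129G>A
F3a	F	m.4071C>T;m.13928G>C
F4	F	m.10915T>C;m.12630G>A
H2	N	m.6674T>C;m.8928T>C;m.14311T>C
Y1	N	m.8392G>A;m.16231T>C
M	N	m.489T>C;m.10400C>T;m.14783T>C;m.15043G>A
D	M	m.4883C>T;m.5178C>A
D4	D	m.3010G>A;m.8414C>T;m.14668C>T
D4e1a	D4	m.3316G>A;m.5964T>C;m.9536C>T
G	M	m.4833A>G;m.8200T>C
M7	M	m.9824T>C
M7b	M7	m.4048G>A;m.5351A>G;m.6680T>C
M8	M	m.4715A>G;m.7196C>A;m.8584G>A;m.15487A>T
Z	M8	m.6752A>G;m.9090T>C;m.15784T>C
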