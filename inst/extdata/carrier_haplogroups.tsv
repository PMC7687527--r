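# Haplogroup assignment used when simulating full-mtDNA variant profiles
# for the case-arm MT-TT carriers. Known-mutation and putative-variant
# carriers follow the lineages reported for the study pedigrees; carriers
# of the four polymorphic variants were not haplogrouped in the source
# study, so their lineages here are synthetic placeholders.
variant_label	haplogroup
m.15927G>A	B
m.15927G>A	B
m.15927G>A	B
m.15927G>A	B
m.15927G>A	B
m.15927G>A	G
m.15927G>A	G
m.15927G>A	F
m.15951A>G	D
m.15951A>G	D
m.15951A>G	D
m.15951A>G	D
m.15900T>C	H2
m.15901A>G	D4
m.15908T>C	F4
m.15924A>G	D4e1a
m.15924A>G	F1a1
m.15924A>G	D4e1a
m.15924A>G	D4e1a
m.15924A>G	F1a'c
m.15924A>G	D4e1a
m.15924A>G	D4e1a
m.15924A>G	F1a1
m.15924A>G	B4
m.15928G>A	M7b
m.15928G>A	Y1
m.15928G>A	Z
m.15931A>C	A
m.15940DelT	Z
m.15943T>C	F3a
m.15943T>C	D4
m.15949G>A	F1a'c
m.15907A>G	F
m.15930G>A	B
m.15930G>A	B4
m.15938C>T	M7
m.15941T>C	B4
m.15941T>C	B4
m.15941T>C	D4
m.15941T>C	G
m.15941T>C	M8
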