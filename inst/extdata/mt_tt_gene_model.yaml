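# Gene model for human mitochondrial tRNA-Thr (MT-TT).
#
# Coordinates are 1-based rCRS (NC_012920.1) positions on the forward
# strand; tRNA positions use the canonical tRNAdb 1-76 numbering so that
# structural sites are comparable across tRNA genes.
#
# `anchors` pins rCRS coordinates to tRNAdb positions at curated sites;
# coordinates between anchors are filled by monotone (left-aligned)
# interpolation. Mitochondrial tRNAs are shorter than the canonical 76-nt
# body, so some canonical positions (e.g. 57-60) have no genomic base.
gene: MT-TT
start: 15888
end: 15953
sequence: GTCCTTGTAGTATAAACTAATACACCAGTCTTGTAAACCGGAGATGAAAACCTTTTTCCAAGGACA
anchors:
  15900: 13
  15901: 14
  15907: 22
  15908: 23
  15924: 39
  15927: 42
  15928: 43
  15930: 45
  15931: 46
  15938: 54
  15940: 56
  15941: 61
  15943: 63
  15949: 69
  15951: 71
# Structural element per tRNAdb position range (cloverleaf annotation).
elements:
  - {from: 1, to: 7, element: acceptor stem}
  - {from: 8, to: 12, element: DHU stem}
  - {from: 13, to: 22, element: DHU loop}
  - {from: 23, to: 25, element: DHU stem}
  - {from: 26, to: 31, element: anticodon stem}
  - {from: 32, to: 38, element: anticodon loop}
  - {from: 39, to: 43, element: anticodon stem}
  - {from: 44, to: 48, element: variable loop}
  - {from: 49, to: 53, element: T-stem}
  - {from: 54, to: 61, element: T-loop}
  - {from: 62, to: 65, element: T-stem}
  - {from: 66, to: 72, element: acceptor stem}
  - {from: 73, to: 73, element: discriminator}
# Watson-Crick stem pairs (unordered tRNAdb position pairs) relevant to
# the annotated variant sites.
pairs:
  - [2, 71]
  - [3, 69]
  - [12, 23]
  - [27, 43]
  - [28, 42]
  - [31, 39]
  - [51, 63]
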