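---
title: "Screening MT-TT variants in a case-control cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening MT-TT variants in a case-control cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttscreen)
```

## The problem

Leber's hereditary optic neuropathy (LHON) is a maternally inherited optic
neuropathy caused by mitochondrial DNA mutations. Most patients carry one of
three primary complex-I mutations (m.3460G>A, m.11778G>A, m.14484T>C), but in
East-Asian cohorts a large fraction of pedigrees lacks all three, and
mitochondrial tRNA genes are candidate mutational hotspots. `mttscreen`
implements the full screening workflow for one such gene, the tRNA-Thr gene
MT-TT (rCRS m.15888–15953): variant calling against the revised Cambridge
Reference Sequence, structural annotation on the tRNA cloverleaf,
cross-species conservation scoring, rule-based pathogenicity classification,
case–control carrier statistics, and mtDNA haplogroup assignment.

The workflow is organised as an analysis: numbered drivers under `analysis/`
run each stage and write plain-text tables under `results/`, while all
computation lives in the package so that it is unit-tested and reusable.

## Reference model

The gene model (`load_gene_model()`) ships as an editable YAML file holding
the 66-nt rCRS MT-TT segment, fifteen curated anchors pinning rCRS
coordinates to canonical tRNAdb positions (1–76 numbering), structural
element ranges, and the Watson–Crick stem pairs. Mitochondrial tRNAs are
shorter than the canonical tRNA body, so the coordinate↔position map is
non-contiguous; between anchors the map is filled by monotone left-aligned
interpolation, and the loader rejects non-monotone or infeasible anchor
sets. The shipped segment was validated internally: every annotated variant
site carries the documented reference allele, the Thr anticodon (UGU) falls
at positions 34–36, and all shipped stem pairs are Watson–Crick in the
reference (including the complete 7-bp acceptor stem).

Two deliberate choices in the shipped model:

* Position 61 is labelled **T-loop** (and left unpaired), matching the
  published annotation of the m.15941T>C site, although canonical numbering
  would place 61 in the T-stem. The pairing table therefore omits (53, 61).
* The pairing table is restricted to the pairs exercised by the annotated
  variant sites plus the acceptor-stem anchor pairs; positions not covered
  by the published table follow canonical cloverleaf ranges and affect only
  the annotation of novel variants.

## Variant calling

`call_variants()` compares a consensus sequence with the reference segment.
Equal-length sequences are compared column-wise; length differences up to
three bases are resolved by exact global (Needleman–Wunsch) alignment via
`Biostrings::pairwiseAlignment()` — the segment is 66 nt, so exact alignment
is cheap and no heuristic mapping is involved. Only substitutions and
single-base deletions are emitted; insertions, larger indels and IUPAC
ambiguity codes raise an error naming the subject (the screen treats all
calls as homoplasmic consensus calls).

Deletions inside homopolymer runs are coordinate-ambiguous. The rCRS T-run
spanning 15940–15944 demonstrates the issue: deleting any of the five Ts
yields the same string. The package normalizes to the **5'-most** rCRS
coordinate of the run by default — the convention under which the observed
T-loop deletion is written m.15940DelT — configurable to 3'-most
(`normalize = "3prime"`, giving m.15944DelT for the same string). The test
suite checks both conventions against a brute-force edit-script enumerator
over every single-substitution and single-deletion input.

## Conservation index

The conservation index (CI) of a site is the percentage of species in a
fixed multi-species alignment (44 vertebrates including human, human row
first) whose base matches the human base. Gap characters count as
non-matching rows by default (`gaps = "exclude"` drops them instead).
Percentages are rounded half-up to two decimals, matching how such tables
are conventionally printed; half-up matters at e.g. 35/44 = 79.5455 → 79.55.

The threshold flag is **inclusive** (CI ≥ 70). The distinction is
unobservable on the study data — the smallest CI in the conserved group is
70.45 — and the inclusive form is stable under re-rounding.

One annotated site (tRNAdb 42, m.15927G>A) has a published CI of 75.45 that
no k/44 can produce; the shipped alignment specification uses 33/44 = 75.00
there. The variant's classification is unaffected because catalog membership
takes precedence (see below).

## Classification rules

Each distinct variant is classified as `known`, `putative` or
`polymorphism`:

1. **known** — present in the shipped catalog of established MT-TT
   disease-associated mutations (m.15927G>A, m.15951A>G).
2. **putative** — under the default rules, (CI ≥ `ci_threshold` **or** a
   deletion) **and** control carrier frequency ≤ `control_freq_cap`
   (defaults 70% and 1%).
3. **polymorphism** — everything else.

The default rule set is the one that reproduces the published variant
grouping: the study's prose criterion ("absent in controls and CI > 70%")
contradicts its own table, in which five putative variants have 1–3 control
carriers and the T-loop deletion has CI 22.73. The prose criterion is
available as `rule_config(preset = "strict_absence")`. The control-frequency
cap of 1% is a round value inside the open interval that separates the
largest putative control frequency (3/376 ≈ 0.80%) from the smallest
control-driven polymorphism (13/376 ≈ 3.46%); any cap in that interval gives
the same grouping. Deletions qualify as structure-disrupting regardless of
CI (`deletion_rescue`), the only route by which a low-CI deletion can be
putative. Classification is a pure function of its inputs and records a
`rule_trace` of every fired test; the suite checks monotonicity (raising the
CI threshold never promotes a polymorphism).

## Cohort statistics

Carrier frequencies are percentages of the arm size, rounded half-up to two
decimals. The case–control comparison is the uncorrected Pearson chi-square
on the 2×2 carrier table, with the two-sided p-value taken from the upper
tail of the chi-square distribution with 1 df. The Yates continuity
correction is exposed as a flag but off by default: on the study's carrier
table (41/311 vs 23/353) the uncorrected statistic gives p ≈ 0.0085, the
published value, while the corrected one gives ≈ 0.012. Tests cross-check
the statistic against `stats::chisq.test(correct = FALSE)` and the p-value
against an independent regularized incomplete-gamma evaluation to six
significant digits.

## Haplogroup assignment

`assign_haplogroup()` performs a deepest-consistent-node search over a
defining-variant tree: each node is scored as (path defining variants
present) − (path defining variants absent); the maximum-score node wins,
ties broken by fewer missing variants, then greater depth, then name. With
every node contributing at least one defining variant, a complete lineage
profile always beats its ancestors and descendants, which makes the rule
exactly testable by round trip; an incomplete deep lineage falls back to its
parent. Back-mutations and recurrent variants are not modeled — a defining
variant is simply present or absent.

The shipped tree is a curated 21-node stand-in covering the East-Asian
lineages observed in the study (A, B/B4, D/D4/D4e1a, F and sublineages, G,
H2, M7/M7b, M8/Z, N, Y1), with defining variants drawn from the
haplogroup-diagnostic markers visible in the study's full-mtDNA profiles and
standard East-Asian markers. M is placed under N so every simulated profile
carries the shared backbone variants; the file format accepts larger
user-supplied trees, and the tree is a declared, replaceable input — not an
import of a reference phylogeny. Macro-haplogroup frequency rows are
percentages at one decimal, half-up.

## What the simulator emulates — and what it does not

The synthetic-data generator defines the study conditions:

* **Cohort** (`lhon_cohort_spec()`): 352 cases / 376 controls; the 15
  observed variants implanted at their observed per-arm carrier counts (41
  case and 23 control carriers), one variant per carrier, carriers assigned
  to seed-shuffled subject ids rather than sampled — the published counts
  are exact observations, so the generator realises them exactly.
* **Alignment** (`lhon_alignment_spec()`): 44 species; per-site match
  counts chosen so the CI at each annotated site equals the published
  value; unspecified sites fully conserved.
* **Profiles** (`generate_profile()`): the defining variants of a lineage
  plus `n_private` random non-defining variants (collisions redrawn). The
  pipeline simulates profiles for the 41 case-arm carriers, with lineages
  for known and putative carriers following the published pedigree
  assignments; the nine polymorphism carriers were not haplogrouped in the
  source study, so their lineages in the shipped assignment are synthetic
  placeholders (documented in the file header).

The simulator does **not** emulate sequencing error, heteroplasmy,
chromatograms, linkage between variants, or population-genetic structure.
Passing tests therefore demonstrate that the analysis logic is correct under
the study's reported counts — not that the variant caller is robust to noisy
real-world traces, nor that the haplogroup classifier would resolve real
PhyloTree-scale lineages.

## Numerical and degenerate-input choices

* Rounding is half-up everywhere a percentage is printed (two decimals for
  carrier frequencies and CI, one for haplogroup rows).
* The chi-square errors on a zero row/column margin; an empty cohort
  produces an all-zero report with `NA` statistics rather than an error.
* Variant calling errors on length differences > 3, on insertions relative
  to the reference, and on ambiguity codes, always naming the subject.
* Problem sizes in the tests and acceptance script: the full 728-subject
  cohort (trivially fast at 66 nt), the complete single-edit enumeration
  (264 inputs), and haplogroup round trips over all 21 nodes × {0, 5, 10}
  private variants × 20 seeds (1,260 profiles) — sizes chosen to exercise
  every branch exhaustively while keeping the default run in seconds.

## Known limitations

* The position map between anchors is an interpolation; only the fifteen
  anchored sites are authoritative, and the numbering gap between sites 56
  and 61 (canonical 57–60 absent) means intermediate assignments near that
  jump are conventional.
* Only MT-TT data ships, though the model format supports any mt-tRNA gene.
* Several figures printed in the source study are not reproducible from its
  own counts (an aggregate putative-carrier percentage, two summary
  percentages, one control-cell percentage, one CI value, and the
  whole-cohort haplogroup row); the package computes the arithmetically
  consistent values instead and none of these is asserted in tests.
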