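---
title: "Typing and lineage classification of PSMB8: models and methods"
author: "psmb8typer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing and lineage classification of PSMB8: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmb8typer)
```

## The biological model

PSMB8 is the inducible catalytic β-subunit of the immunoproteasome. It is
translated as a precursor: a short propeptide is cleaved at a conserved
TTTL motif, and the first threonine of that motif — the catalytic Thr1 —
becomes residue 1 of the mature protein. Every position referenced in this
package uses this mature numbering; the package's `MatureMap` class is the
bridge between precursor and mature coordinates, and `detectMatureStart()`
anchors it by locating the first TTTL whose start falls within the first
90 precursor residues (proteasome β-subunit propeptides are short; the
window prevents spurious internal TTTL matches and is configurable).

Two properties of a PSMB8 sequence are deliberately kept distinct:

* **Type** — the identity of mature residue 31, which sits inside the S1
  substrate-binding pocket and shifts cleavage preference. The vocabulary:
  A31/V31 → A type, F31/Y31 → F type, S31/T31 → S type (threonine is
  grouped with serine; both present a small linear hydroxyl group),
  K31 → K type (a positive charge unique among reported alleles). Any
  other residue is reported as `other` with the literal residue attached,
  so a novel allele can never be silently collapsed — this is exactly how
  new types are noticed. `X`, truncation, or a gap-mapped site give
  `undefined`.
* **Lineage** — membership in one of two ancient allelic clades (A and F)
  maintained by trans-species polymorphism. Because a type can be regained
  by point mutation within the other lineage, residue 31 alone cannot
  determine lineage.

Lineage is therefore estimated twice and both calls are always reported:

1. `classifyLineage()` counts matches of the eight diagnostic residues
   (positions 13, 99, 147, 150, 156, 188, 189, 194; references
   A = I,S,M,E,G,C,K,E and F = M,T,L,P,A,S,Q,D) and takes the majority.
   Undefined positions match neither side, and ties return `ambiguous`
   rather than a forced call.
2. `assignLineageByClade()` walks from the query tip of the rooted
   phylogeny toward the root and returns the label of the first ancestor
   whose labeled reference descendants are uniform; a mixed set can never
   become uniform further up, so such queries are `unresolved`.

When the two disagree, the report flags the row and the phylogenetic call
is used as the recommended `lineage_call`: diagnostic residues are eight
point characters, while clade placement integrates the whole alignment.

## Alignment machinery

Screening and coordinate mapping need deterministic alignments, so the
affine-gap dynamic programming (Gotoh) is implemented in C++ with an
explicit tie-break order — substitution, then gap in the first row, then
gap in the second — applied both when cells are maximised and during
traceback. The default scoring is BLOSUM62 with gap open −11 and extend
−1, the canonical protein BLAST parameters; a gap of length $L$ scores
$\mathrm{open} + (L-1)\,\mathrm{extend}$. The test suite checks the global
aligner against a brute-force linear-gap DP oracle (exhaustively for all
string pairs up to length 3 over a 4-letter alphabet, and on seeded random
pairs up to length 6 — the full cross product at length 6 is ~30M pairs
and adds nothing beyond the sampled coverage) and against
`Biostrings::pairwiseAlignment()` for affine scores in both modes.

`progressiveMsa()` is a deliberately simple progressive aligner: a guide
tree from UPGMA clustering of 3-mer count distances, then profile–profile
global alignment with sum-of-pairs expected scores, where a gap fraction
scores `gapExtend` against residue mass and zero against gap mass. It is
deterministic for a fixed input order and entirely adequate for the
≤ 60-sequence, high-identity alignments this workflow produces; it is not
a Clustal replacement for divergent data.

The screening threshold replaces a BLAST e-value rule with
score ≥ 100 **and** identity ≥ 0.40 over aligned columns (gap columns are
excluded from the identity denominator). E-values need a database-size
model that adds nothing here, because candidates are re-validated
downstream; both thresholds are exposed in `screenConfig()`.

## QC and the undefined-31 rule

`applyQc()` applies checks in a fixed order and records the first failure,
so rejection reasons are deterministic: `no_TTTL`, `truncated_before_31`
(mature length < 31), `undefined_31`, `decoy_family` (best screening hit
is PSMB5), `duplicate` (identical mature protein within the same group;
candidates are processed in id order so "first by id" is exact). Record
conservation holds at every stage: input ids = kept ids + rejected ids
(contigs with no retained ORF are logged as `no_candidate`).

Residue 31 is read through an alignment, not by direct indexing: the
reference mature protein is globally aligned to the query mature and
reference position 31 is mapped across (`mapRefPosition()`). A deletion
spanning the site maps to a gap and the sequence is reported undefined —
the behaviour needed for real alleles whose residue 31 is lost to indels.
One caveat: when a deletion's flanking residues resemble the deleted ones,
the optimal alignment may slide the gap by a column and rescue a residue;
across simulations this affects on the order of 1% of deletion-bearing
sequences and is inherent to alignment-based coordinate transfer.

## Phylogeny

Distances are p-distances over columns where both rows carry residues,
optionally Poisson-corrected ($-\ln(1-p)$; saturation is an error, not a
silent `Inf`). Neighbor joining follows Saitou–Nei with the standard
Q-criterion; ties take the lexicographically smallest index pair, and
negative branch-length estimates are clamped to zero with the deficit
moved to the sister branch. NJ is exact on additive matrices, which the
tests exploit: random trees provide additive matrices, and a brute-force
least-squares fit over all 3 (4-taxon) or 15 (5-taxon) topologies is the
oracle. Maximum-likelihood inference is intentionally out of scope; the
quantities this workflow needs — lineage monophyly and clade membership —
are stable under NJ at these divergences.

Bootstrap support is the classic nonparametric column resample: rebuild
the NJ tree per replicate and report the percentage of replicates
containing each internal bipartition of the point tree. Rows are sorted by
id before any computation, so supports are invariant to input order for a
given seed (default 200 replicates, seed 42). Rooting places the root at
the midpoint of the branch separating the (required monophyletic) PSMB5
outgroup from the ingroup; node labels are treated as edge-associated so
supports stay attached to the correct bipartition across rerooting.

## The synthetic transcriptome generator

The generator exists so that every stage has ground truth. Its fixed
templates are pinned constants: A- and F-lineage precursors (20-residue
propeptide, 204-residue mature protein starting TTTL, diagnostic residues
embedded per lineage, mature identity 0.86 between lineages) and a
PSMB5-like decoy (30-residue propeptide — real PSMB5 shares the catalytic
threonine motif at a different offset — at ~0.54 identity to both). Coding
sequences come from a fixed preferred-codon table; Leu/Ser/Thr/Ile use
CTA/TCA/ACT/ATC so the antisense frames are salted with stop codons, and a
deterministic synonymous-swap pass removes any remaining shifted-frame ORF
of ≥ 100 residues from the templates. Each emitted contig is certified to
contain exactly one ORF ≥ 100 residues at the truth coordinates (a TAG
seals the 5' UTR in frame so the ORF start is well defined), on a randomly
chosen strand.

Default group structure mirrors a two-species holostean study: 35
A-lineage sequences (8 A/GCC, 24 S with T31/ACC, 3 K/AAG) and 22 F-lineage
sequences (6 F/TTC, 16 S/TCT), plus 3 decoys (as many as the outgroup
sequences a typical analysis carries) and 5 random contigs; UTRs are 100
nt. Substitutions are nucleotide-level at rate `mu` (default 0.02 per
site, a realistic within-population transcript divergence) with a 2:1
third-position bias, giving a natural synonymous/nonsynonymous mixture.
Codons for the start, TTTL, the S1 pocket and the diagnostic positions are
never mutated, and draws creating a stop codon or a premature TTTL are
rejected — the generator must control the labels the pipeline estimates,
at every `mu` in [0, 0.3]. An optional per-sequence indel deletes the 6 nt
spanning mature codons 30–31 to produce the undefined-31 case. All
randomness flows from the single mandatory spec seed.

What passing tests show — and what they do not: the simulation reproduces
the *structure* the pipeline assumes (one clean ORF per contig, uniform
template length, no assembly artifacts, no paralogous gene families beyond
one decoy, mutation without selection). Recovery rates of 100% on these
data validate the machinery, not performance on real transcriptomes with
fragmented contigs, chimeras, or allelic assembly collapse.

## Numerical and design choices

* Coordinates: ORFs are 0-based half-open on the forward strand; minus
  strand ORFs carry the reverse-complement slice. Mature positions are
  1-based from Thr1. `MatureMap` stores the 0-based precursor index of
  Thr1.
* Translation: standard genetic code only (vertebrate data); codons with
  ambiguity codes give `X`; trailing partial codons are dropped.
* Problem sizes in the shipped tests: cohorts of 12–65 contigs, 20 seeds
  for exact-recovery checks, 200 bootstrap replicates for the monophyly
  check, 25 additive-matrix draws per taxon count — sizes at which each
  property is already unambiguous.
* Degenerate inputs: empty contig sets, decoy-only and random-only inputs
  return empty but well-formed reports; saturation and zero-overlap
  distances, non-monophyletic outgroups, unknown ids and empty sequences
  raise errors naming the offending record.
* `runPipeline()` labels tree references by name (`ref_PSMB8_A`,
  `ref_PSMB8_F`, `ref_PSMB5`); user-supplied reference sets should follow
  the same convention for clade labeling to apply.

## Known limitations

Genome-scale screening (this package aligns every ORF against every
reference exhaustively), intron-containing queries, ML tree inference,
3-D structure modeling and kinase-motif scanning are out of scope.
Progressive alignment quality degrades below ~40% identity, where a
dedicated MSA tool should be substituted before the distance stage.
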