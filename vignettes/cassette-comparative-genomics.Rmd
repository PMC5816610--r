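---
title: "Methods: cassette comparison, footprinting and relative expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cassette comparison, footprinting and relative expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassettecompare)
```

This vignette is the package's own account of its methods: the models and
conventions each stage implements, the parameters that matter and why
their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the design choices that were genuinely open.

## Gene tables and coordinates

Everything downstream works on a plain gene table: one row per gene with
0-based half-open coordinates (`start` inclusive, `end` exclusive).
Half-open coordinates make the intergenic gap a single subtraction,
`start[i+1] - end[i]`, with overlapping genes yielding negative gaps and
no off-by-one cases. GFF3 and GenBank are 1-based inclusive and are
converted on input; writers emit each format's own convention. A "gene"
is any `gene` or `CDS` feature with a distinct locus tag; when both are
present the CDS coordinates win, because intergenic distances concern
coding regions. Genes nested inside another gene are kept as ordinary
list members in start order — deterministic behaviour on messy
annotations matters more than any particular treatment of nesting.

## Cassette assembly

A cassette is a maximal run of chromosomally adjacent genes whose
pairwise gaps are all **strictly below `max_gap` = 300 bp**: a 299 bp gap
joins, a 300 bp gap splits. Strand and gene order play no role, and
negative gaps (overlaps) always join. The threshold is the standard
operon-neighbourhood proxy for co-transcription at this scale.
`min_genes` defaults to 2 — a single isolated gene is not a cassette,
though the parameter is exposed for sensitivity analysis. Replicons are
treated as linear by default; setting `circular = TRUE` additionally
tests the wrap-around gap and merges the two terminal runs when it
passes. Assembly is a single left-to-right chaining pass, so its
correctness is easy to state (partition, maximality, strand-blindness,
idempotence) and is tested against an exhaustive boundary-check oracle
and igraph connected components on a thousand random layouts.

## Fingerprints and the matching model

Each gene's label set is the union of three kinds of labels:

* **`ec3`** — each annotated EC number truncated to its first three
  fields, kept only when all three are defined numerals. Three shared
  fields mean the same reaction type; `2.7.-.-` carries no usable type
  and is dropped. Multi-valued EC annotations all contribute (set
  semantics).
* **`role`** — case-insensitive keyword matching on the product text.
  The default vocabulary is `{transporter, transcription_factor}` with
  keyword lists covering permease/PTS-style transporter names and the
  six major local-regulator families of enteric sugar metabolism (LacI,
  ROK, DeoR, AraC, GntR, TetR). The rules are data, not code: any
  vocabulary can be supplied.
* **`cog`** — a COG identifier, used as an optional refinement: it only
  ever matches when both genes carry it.

Two genes are *compatible* when their label sets intersect; the reported
shared label follows the kind priority `ec3 > cog > role` so output is
deterministic. The functional match of two cassettes is the cardinality
of a **maximum bipartite matching** on the compatibility graph, computed
by augmenting-path search with genes processed in chromosomal order.
Maximum matching rather than greedy multiset intersection matters because
genes can carry several labels; a greedy pairing can block a feasible
assignment (there is a unit test exhibiting exactly that). Ties among
maximum matchings resolve toward the lowest gene indices, which is why
the packaged example pairs the first of the two *yih* transporters.

The cross-taxon search enumerates candidate combinations by intersecting
observed fingerprints — the matched combination of every cassette pair
from different taxonomic groups — never by enumerating a blind powerset.
Each candidate's support is then verified against *every* cassette by a
cover matching (can the combination's labels be assigned one-to-one to
distinct genes?), combinations below `min_groups` distinct groups are
dropped, and strict sub-multisets of kept combinations are pruned.
Defaults `min_size = 4`, `min_groups = 2` are deliberately permissive;
the packaged six-gene example is reproduced at `min_size = 6`. Group
identity is the `taxon_group` field, family-level in the fixtures
(Enterobacteriaceae vs Bacilli).

The packaged fixture encodes the two cassettes with per-gene labels
exactly as published, including the isomerase label `2.3.1` — EC class
2.3.1 formally denotes acyltransferases, but the matching rule is
label-agnostic and the fixture is not silently "corrected".

## Regulatory-region footprinting

**Intergenic extraction.** One region per adjacent gene pair whose gap is
at least `min_length` = 40 bp (shorter gaps cannot hold a promoter),
extended `extension` = 100 bp into both flanking gene bodies to absorb
mis-annotated start codons, clipped only at replicon ends.

**Alignment.** Orthologous regions are aligned by a center-star
progressive scheme: the first sequence is the designated reference, every
other sequence is globally aligned to it (Gotoh affine-gap DP, match +1,
mismatch −1, gap open −5, gap extend −1, a gap of length L costing
`open + (L−1)·extend`), and the pairwise alignments are merged on
reference coordinates under "once a gap, always a gap". Traceback
tie-breaks are fixed (diagonal, then gap in the second sequence, then gap
in the first), so alignments are reproducible. For closely related
intergenic regions — the only intended use — the star topology loses
essentially nothing against heavier progressive aligners, and the DP core
is validated against brute-force enumeration of all alignments of short
strings. The DP is implemented in C++ (Rcpp); sequences are capped at
5,000 nt.

**Conservation.** Per reference (ungapped) column, identity is the
fraction of sequences, reference included, whose residue equals the
reference residue; gaps count as mismatches, and insertion columns carry
no reference position. A site's conservation is the **mean** column
identity over its span — the mean rather than the minimum, to be robust
to single-column noise.

**PWM scanning.** A motif is either a 4×L log-odds matrix or an IUPAC
consensus expanded with pseudocount 0.25 against a uniform background
(each consensus position spreads one count over its allowed bases). With
those defaults a specified position scores `log2(2.5) ≈ 1.32` bits on a
match, −1 bit on a mismatch, and `N` positions score zero — so the
default CRP model `TGTGA-N6-TCACA` has a 13.2-bit maximum. Scanning
covers both strands of the window from −250 to +50 around the anchored
transcription start (clipped to the region), and reports windows scoring
at least 60% of the motif's maximum — a threshold chosen to admit
two-mismatch variants of the CRP consensus while keeping the random-hit
expectation per 300-nt window below one. TSS-relative coordinates have
+1 at the transcribed base and no position 0; a site's center is the
midpoint of its span computed on the gapless scale, so even-length sites
get half-integer centers and a 22-position site spanning −52..−31 is
centered at −41.5 — the Class II CRP geometry. Spans crossing the absent
zero take the negative branch on a fractional midpoint (−3..+3 reports
−0.5); such spans do not arise for upstream regulatory sites.

**Ranking.** Hits are ranked by the sum of their PWM-score rank and their
conservation rank (ties within each component rank by minimum), with
residual ties broken by higher score, then by the more upstream position.
This keeps "highly conserved sites with best scores" at the top without
committing to a weighting between bits and identity fractions.

## ΔΔCt quantification

Per replicate, ΔCt is the target Ct minus the **arithmetic mean** of the
reference genes' Cts in the same replicate — with two control genes the
combination rule had to be chosen, and the per-replicate mean is the one
that makes fold changes invariant to any gene-independent Ct shift of a
sample (a property the suite tests). ΔΔCt is the condition's mean ΔCt
minus the reference condition's, and the fold change is `2^−ΔΔCt`, with
amplification efficiency fixed at 2 (efficiency-corrected variants are
out of scope). The standard deviation combines the two conditions'
replicate ΔCt standard deviations in quadrature and maps through the
exponential at first order (`sd_fold = fold · ln2 · sd_ΔΔCt`); this is
the classical replicate-spread propagation, which is conservative
relative to a standard error of the mean. A single replicate reports
`NA`, not zero. The reference condition defaults to glucose, the
standard rich carbon source fold changes are expressed against.

## The synthetic-data generators

All three generators are seeded, emit ground truth sufficient to score
recovery without re-derivation, and are byte-identical under a fixed
seed.

* `simulate_genomes()` writes GFF3+FASTA replicons whose gaps follow a
  two-component mixture (default: 60% "within-cassette" gaps of
  20–299 bp, 40% "between-cassette" gaps of 300–2,000 bp, gene lengths
  300–1,500 bp — magnitudes typical of bacterial chromosomes). Planted
  cassettes are inserted as consecutive runs with sub-300 bp internal
  gaps and ≥300 bp flanks, so their assembly is unambiguous. Background
  annotation draws from a 20-entry EC pool that includes the four
  reaction types of the packaged example, and from a product pool with
  no role keywords, so planted role genes are the only role carriers by
  default.
* `simulate_ortholog_regions()` uses a star phylogeny with the reference
  at the center: the first sequence is the unmutated ancestral proxy and
  each ortholog is an independently mutated copy (substitutions only, to
  one of the other three bases uniformly; no indels). The planted motif
  span mutates at `divergence_inside` (default 0.02) against
  `divergence_outside` elsewhere — the conservation contrast that
  phylogenetic footprinting detects. With the reference ancestral, the
  expected mean profile identity is `1 − d·(n−1)/n`, which is what the
  parameter-recovery tests check; the conservation-recovery run uses
  divergence 0.1 with 8 orthologs over 1,000 columns, where that
  expectation sits within 0.013 of `1 − d`. Defaults plant the 16-nt CRP
  consensus at TSS-relative span [−49, −34] (center −41.5) in a 300-nt
  region with the TSS at offset 250, so the −250/+50 window covers the
  whole region.
* `simulate_ct_table()` uses the standard 3 biological × 3 technical
  replicate design with Gaussian technical noise (default sd 0.2
  cycles, a realistic qPCR technical spread); reference genes are
  condition-independent and targets are shifted by `−log2(fold)`. The
  default plants a 4-fold activation, a 2-fold repression and a null
  gene.

What the simulators deliberately do **not** emulate: tree-structured
phylogenies (star only), indels in intergenic regions, annotation errors
(wrong ECs, missing genes), genome-scale databases (hundreds of species,
tens of thousands of cassettes), and sequencing artefacts. Passing
recovery tests therefore demonstrates the correctness of the
*computations* under clean inputs, not robustness to the full messiness
of public annotation databases.

## Problem sizes and validation choices

The validation suite runs at fixed sizes chosen to make the statistics
meaningful at interactive cost: 1,000 random layouts for the assembly
oracle (with 299/300 bp edge gaps over-sampled), 500 random cassette
pairs of up to 7×7 genes against brute force over all injective
assignments, 200 seeded footprinting simulations at 6 orthologs / 300 nt
/ divergence 0.2 outside vs 0.02 inside the 16-nt motif, 500 seeded Ct
tables for sd calibration, and 1,000 columns for divergence recovery.
`scripts/acceptance.R` recomputes all of these from a single `--seed`.

## Known limitations

* GenBank parsing covers the common single-interval and
  `complement()` locations plus the qualifiers the pipeline uses; it is
  not a full flat-file grammar. GFF3 goes through rtracklayer and is the
  preferred input.
* The conserved-combination search generates candidates from *pairwise*
  maximum-matching intersections; a combination supported only as the
  mutual intersection of three or more cassettes (but no pair) would be
  missed. No such case arises in the fixtures or simulations.
* Maximum matching makes one-to-one pairing explicit; on cassettes with
  heavily multi-valued labels other published analyses may have used
  looser label-overlap criteria, which maximum matching subsumes for the
  packaged example.
* Promoter *prediction* is out of scope: transcription starts are inputs
  (mapped elsewhere), and the footprinting stage only scores and ranks
  candidate factor sites around them.
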