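---
title: "Methods: microsatellite mining, cross-species transfer, synteny and diversity"
author: "ssrmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite mining, cross-species transfer, synteny and diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## Overview

`ssrmine` implements a genome-wide simple-sequence-repeat (SSR) marker
pipeline of the kind used to characterize plant genomes such as the
cucurbits: mine microsatellites from an assembly, design flanking PCR
markers, screen the markers against related genomes by electronic PCR to
find cross-species transferable (single-product) markers, use the shared
markers to call collinear and inverted syntenic blocks between
chromosomes, and apply a marker panel to a germplasm collection through
codominant diversity statistics, a UPGMA dendrogram and the Evanno
delta-K criterion for the number of populations.

Real genome assemblies and germplasm genotypes are large, external and in
part unpublished, so the package validates every stage on synthetic data
with planted ground truth instead: each generator writes a planting record
that fully determines its output, and the test suite checks recovery
against that record and against independent brute-force oracles. This
vignette documents the models, the tunable parameters and the design
choices made where the underlying procedure is under-specified.

## SSR detection model

A microsatellite is a maximal perfect tandem array of a 2–8 bp motif.
Mononucleotide runs are excluded because they cannot be told apart from
sequencing or assembly error. Each unit-length class must reach a minimum
total array length:

```{r}
motif_classes()
```

Thresholds are in bp; the minimum number of complete units is the ceiling
of `min_total_length / unit_length`. The tetranucleotide threshold (18 bp)
is not a multiple of 4; since repeat counts are integers the ceiling rule
(5 units, 20 bp) is the only reading consistent with an 18 bp minimum.

Detection rules (`scan_sequence()`):

* coordinates are 1-based inclusive everywhere and span complete units
  only;
* a maximal run is reported exactly once, under its shortest generating
  unit — a run whose apparent motif is itself periodic (e.g. ATAT) belongs
  to the shorter unit's class; overlapping runs of *different* families
  are all reported;
* IUPAC ambiguity codes terminate runs: an array containing N is not a
  bona fide tandem repeat;
* motif families are normalized by `canonical_motif()`: the smallest
  string over all cyclic rotations of the motif and of its reverse
  complement (so AG ≡ GA ≡ CT ≡ TC), which is the grouping used in motif
  composition tables.

Neighbouring arrays separated by at most `max_interruption` bases merge
into a compound locus (`merge_compound()`). The interruption limit is not
fixed by the procedure this mirrors; the conventional 100 bp default is
used and the parameter is exposed.

## Primer design

`design_marker()` is a deliberately simple, fully deterministic picker,
not a re-implementation of Primer3 (whose untouched internal defaults are
not recoverable): both primers must lie wholly outside the repeat array,
the amplicon must contain the array, and the pair must satisfy the
published constraint window — product 100–300 bp, primer length 18-20-24
nt (min-opt-max), Tm 50-55-60 °C — plus fractional GC in 0.20–0.80 and no
perfect self-complementary stretch of ≥ 8 bp (a conservative self-dimer
screen). Among feasible pairs the best is chosen by summed `|Tm − 55|`,
then summed `|length − 20|`, then leftmost position, so identical inputs
always give identical pairs.

Melting temperatures use the unified nearest-neighbor thermodynamic table
(SantaLucia, PNAS 1998) with fixed conditions of 50 mM monovalent cation
and 50 nM annealing oligo, the entropic salt correction
`ΔS + 0.368 (n−1) ln[Na+]`, and `Tm = 1000·ΔH / (ΔS + R ln(C/4)) −
273.15`. Only the Tm *window* is dictated by the protocol being mirrored;
the model and its concentrations are a package choice, frozen in one
parameter table and cross-checked in the tests against an independent
recomputation.

## Electronic PCR and the asymmetric mismatch rule

A primer binds where an ungapped alignment satisfies (`match_rule()`):

* mismatches only within the 5′-most `five_prime_window` bases (default
  5), at most `max_5prime_mismatches` (default 5) of them;
* every position outside that window — the whole 3′ portion, including
  the 3′ terminus — matches exactly;
* overall identity ≥ `min_identity` (default 0.90).

The window size is not stated by the rule's source; 5 nt is the smallest
window consistent with "up to 5 mismatches at the 5′ end", and making the
entire remainder exact subsumes any stricter 3′-terminal condition. The
two caps are enforced jointly: for a 20-mer the identity floor admits at
most 2 mismatches even though the window would allow 5. Indels are never
allowed — primer extension tolerates none at the 3′ end, and the ungapped
rule keeps results deterministic and identical to the brute-force oracle.

`amplify()` pairs sites in convergent orientation (one primer on each
strand, 3′ ends facing) whose outer span — 5′ end of the plus-strand site
to the 5′ end of the minus-strand site — lies within `product_bounds`.
The bounds are not fixed by the mirrored protocol; the default is a
permissive 50–3000 bp. Markers with exactly one product on a target
genome are classified cross-species transferable
(`classify_transferability()`); the intersection of single-copy sets over
several targets (`intersect_transfer_sets()`) gives the markers shared by
all genomes. Gene-context annotation is interval overlap (≥ 1 bp) of
amplicons against GFF3/BED features — a documented surrogate for
similarity searches against transcript databases.

## Syntenic blocks

Markers placed on two genomes (source position = SSR midpoint, target
position = amplicon midpoint; single-copy markers only) are walked per
source chromosome in source order after assigning each marker its
positional rank within its target chromosome. A block extends while the
target chromosome is unchanged and target ranks advance by exactly one in
a fixed direction; a configurable `max_rank_gap` (default 0) allows
skipping interleaved markers. Runs of at least `min_block_markers`
(default 3) become blocks, collinear when ranks increase and inverted
when they decrease; shorter runs are dropped (logged via the partition
property: retained markers belong to exactly one block).

The exact block-delimiting rule of comparative-mapping studies is rarely
stated (gap tolerance, lone out-of-place markers). Plain monotonicity
without rank adjacency would attach the first marker of an inverted
segment to the preceding collinear run, so "continuous positions" is
operationalized as *rank-adjacent* monotone runs; with the default gap of
0 this recovers planted inversion breakpoints exactly and is symmetric
under swapping the two genomes. Because this is a documented choice
rather than a claim of equivalence to any published block count, genome-
scale block numbers are not treated as reproduction targets. Markers on
unanchored scaffolds (e.g. `chr0`) count for transferability but are
excluded from synteny (`drop_seq_ids`). Conserved three-genome blocks are
pairwise intersections of block member sets on the shared source genome
with the same ≥ 3 member minimum.

## Diversity statistics

For allele frequencies `p` at a locus (computed over non-missing
genotypes; missing calls are excluded pairwise and never imputed):
`Na = |alleles|`, `Ne = 1/Σp²`, `He = 1 − Σp²`, `I = −Σ p ln p`,
`Ho = heterozygotes / scored genotypes`, and PIC in the Botstein (1980)
form `1 − Σp² − Σ_{i<j} 2 p_i² p_j²`. Some legacy reports print "PIC =
ΣPij²", which is expected homozygosity and inconsistent with typical
printed PIC ranges for polymorphic markers; it is available only as the
explicitly named `"legacy"` variant (with `"he"` as a further variant),
while Botstein is the default.

The accession distance is the allele-sharing distance
`d(a,b) = 1 − mean over jointly scored loci of (shared alleles / 2)`,
counting multiplicity. The software this mirrors names only a
"codominant genotypic" distance without defining it; allele sharing is
the standard codominant choice and is documented as such.

`upgma()` is written out in full (unweighted average linkage with
leaf-count-weighted updates) rather than delegated, because deterministic
tie-breaking is part of its contract: equal-distance merges are resolved
by the lexicographic order of the clusters' sorted leaf-label sets.
The tests cross-check it against average-linkage `hclust()` and verify
ultrametricity to 1e-9 and exact reproduction of ultrametric inputs.

The Evanno statistic is `ΔK(K) = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))`,
with second differences taken on per-K replicate means — replicates are
not paired across K, so a per-replicate second difference is undefined —
and the standard deviation across replicates at K. It is undefined at the
endpoints of the K range; a zero replicate standard deviation yields an
infinite sentinel with a warning (zero curvature with zero sd reports 0).
The argmax over interior K estimates the number of populations. The MCMC
clustering that produces the log-probability tables is out of scope; the
tables come from external runs or from `simulate_lnpd()`.

## Synthetic data and what it does (not) show

`make_ssr_genome()` plants loci in a uniform A/C/G/T background whose
incidental threshold-passing tandem runs are rejection-sampled away, with
junction bases constrained so planted arrays can neither shift nor
extend. This clean-background property is what makes recall = precision
= 1.0 a meaningful expectation; real genomes are not clean, so those
exact figures certify the scanner's logic, not field performance on real
assemblies. Defaults (100 kb, 50 loci, uniform class mix, ≥ 30 bp
spacing) are the scale at which the property tests run.

`derive_partner_genome()` applies segmental inversions (reverse
complemented in place) and translocations (segment appended to another
chromosome), then point substitutions. Segment boundaries fall midway
between marker protection zones so no planted locus or primer-bearing
flank is cut, and each segment carries ≥ 5 markers inside ≥ 3 untouched
context markers so blocks are identifiable. Mutations avoid ±350 bp
around each planted locus — a superset of any primer footprint for
≤ 300 bp amplicons — unless `stress = TRUE`, which is how transfer loss
versus mutation rate is measured. The bookkeeping labels every marker
with its segment, and `planted_block_truth()` converts those labels into
the expected block partition without reference to the block caller's rank
logic. No attempt is made at coalescent-realistic genome evolution or
linkage modelling.

`simulate_genotypes()` draws per-population allele frequencies from a
symmetric Dirichlet (`alpha = divergence` per allele; the single knob for
differentiation) and genotypes under Hardy–Weinberg equilibrium within
populations. Defaults — K = 2, 67 accessions per population, 32 loci,
5 alleles per locus, divergence 0.2 — emulate the scale of a
134-accession, 32-marker germplasm panel with a strong two-population
structure; they are not a demographic model of any real collection.
`simulate_lnpd()` plants a single slope break at the true K (defaults:
K = 1..10, 20 replicates, slopes 600 → 30, noise sd 40, magnitudes in the
range typical of such runs).

## Numerical and interface conventions

* One shared 1-based inclusive coordinate convention across all tables;
  BED output converts to 0-based half-open.
* All tables are header-bearing TSV with `#` comments; FASTA via
  Biostrings; GFF3 output records one `microsatellite` feature per locus;
  Newick via ape; planting records as JSON.
* Marker identifiers are a configurable prefix plus zero-padded ordinal
  in genome order (`ClSSR00001` style).
* Identity thresholds compare with a 1e-9 slack against floating-point
  edge effects (e.g. the 90 % cap on a 20-mer is exactly 2 mismatches).
* All generators take an integer seed and are byte-deterministic given
  identical parameters.

## Problem sizes used in validation

The shipped validation runs at deliberately moderate scale, chosen so the
whole suite exercises every contract in minutes: scanner
recall/precision on one 100 kb genome with 50 planted loci plus
brute-force agreement on 50 × 2 kb sequences; electronic PCR against
brute-force oracles on 20 × 100 kb targets × 50 markers with spliced-in
boundary-case binding sites; 20 seeded rearrangement simulations for the
block caller; 20 seeded two-population panels (134 × 32) for dendrogram
recovery and 100 seeded LnP(D) tables for the elbow criterion; and an
end-to-end three-genome run (3 × 60 kb chromosomes, 36 markers). Sizes
scale up linearly if heavier validation is wanted.

## Known limitations

* The scanner models perfect and compound repeats only; imperfect
  (mismatch-containing) arrays are out of scope.
* The primer picker ignores hairpins, heterodimers and positional
  nucleotide preferences; it is not claimed equivalent to Primer3.
* Electronic PCR is sequence identity, not thermodynamics; degenerate
  primers are unsupported.
* Block calling operates on marker orders, not sequence alignment; no
  breakpoint refinement between markers.
* Admixture estimation, bootstrap support and AMOVA are out of scope;
  only the delta-K post-processing of externally produced log
  probabilities is implemented.
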