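# ssrmine

Genome-wide microsatellite (SSR) marker development and application, as an
R package: mine perfect and compound SSRs from an assembly, design
flanking PCR markers, screen them against related genomes by electronic
PCR to find cross-species transferable markers, call collinear and
inverted syntenic blocks from the shared markers, and analyse germplasm
panels with codominant diversity statistics, UPGMA dendrograms and the
Evanno ΔK criterion. Every stage is validated on synthetic genomes and
genotypes with planted ground truth.

## Who it is for

Plant and comparative genomicists building SSR marker resources from a
draft assembly (the workflow popularized by genome-wide surveys in
cucurbits and other crops), and anyone needing a tested, scriptable
implementation of the individual stages: MISA-style repeat scanning,
primer picking under the classic 100–300 bp / 18-20-24 nt / 50-55-60 °C
constraints, e-PCR with an asymmetric 5′-mismatch rule, marker-based
synteny, and GenAlEx-style diversity summaries.

## The core rules and statistics

* **SSR detection** — maximal perfect tandem arrays of 2–8 bp motifs with
  per-class minimum lengths 18/18/18/20/24/21/24 bp (di → octo, hence ≥
  9/6/5/4/4/3/3 complete units); mononucleotides excluded; motif families
  normalized over cyclic rotation and reverse complement (AG/CT);
  neighbouring arrays ≤ 100 bp apart merge into compound loci.
* **e-PCR match rule** — ungapped binding with up to 5 mismatches confined
  to the 5′-most 5 nt, exact match everywhere else (including the 3′
  terminus) and ≥ 90 % overall identity; a marker is transferable to a
  genome when it yields exactly one product there.
* **Syntenic block** — ≥ 3 shared markers consecutive on one chromosome in
  each genome with strictly monotone, rank-adjacent target order;
  collinear if order agrees, inverted if reversed.
* **Diversity** — per locus: Na, Ne = 1/Σp², Ho, He = 1 − Σp²,
  I = −Σp ln p, PIC (Botstein) = 1 − Σp² − Σ_{i<j} 2p_i²p_j²;
  allele-sharing distances, UPGMA with deterministic tie-breaking, and
  ΔK = |L″(K)| / sd(L(K)) with the argmax over interior K.

## Worked example

```r
library(ssrmine)

sim <- make_ssr_genome(length = 50000, n_loci = 15, min_gap = 900, seed = 2)
catalog <- scan_genome(sim$genome)
markers <- design_markers(sim$genome, catalog, verbose = TRUE)
#> designed 15/15 primer pairs (100.00%)

markers[1, c("marker_id", "fwd_seq", "rev_seq", "expected_product_bp")]
#>    marker_id              fwd_seq             rev_seq expected_product_bp
#> 1 ClSSR00001 ACCTCGACAAGAGGGTCTGG GGGGAGGAGGGTCGAACAA                 224

classify_transferability(markers, sim$genome)
#> transfer_table: 15 markers tested; 15 single-copy (100.00%), 0 multi-copy, 0 without product
```

Every designed pair re-amplifies exactly its own locus (the single-copy
count equals the marker count), which is the round-trip soundness check
the test suite enforces; against a diverged partner genome the same call
yields the cross-species transferable subset.

The `analysis/` directory holds the full narrative workflow over a
three-genome synthetic fixture — `01_simulate_data.R` through
`06_diversity.R` — each a thin driver over the package functions that
prints what it found and writes its tables under `results/`. Running them
in order ends with, among other things, a planted-truth comparison like:

```
partner 1: 9 blocks (2 inverted); planted truth recovered: TRUE
UPGMA top split vs planted populations: purity 1.000
best K (max delta-K over interior K): 2
```

## Package layout

* `R/` — scanning (`scan_sequence`, `merge_compound`, `canonical_motif`,
  `summarize_catalog`), design (`design_markers`, `melting_temperature`),
  e-PCR (`find_binding_sites`, `amplify`, `classify_transferability`,
  `intersect_transfer_sets`, `annotate_markers`), synteny (`call_blocks`,
  `chromosome_correspondence`, `intersect_blocks`, `export_links`),
  diversity (`locus_stats`, `distance_matrix`, `upgma`, `evanno_delta_k`),
  generators (`make_ssr_genome`, `derive_partner_genome`,
  `simulate_genotypes`, `simulate_lnpd`) and format IO (FASTA, GFF3, BED,
  TSV, Newick, JSON planting records).
* `src/` — the Rcpp primer-site scanner.
* `vignettes/ssr-pipeline-methods.Rmd` — the methods account: models,
  parameter defaults, design decisions and limitations.
* `tests/testthat/` — unit, property and acceptance tests, with
  brute-force oracles in `helper-oracles.R`.
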