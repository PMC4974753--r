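#!/usr/bin/env Rscript
# Build the synthetic study fixtures with known ground truth: a source
# genome with planted SSR loci, two rearranged and diverged partner genomes
# (emulating two related species), a two-population genotype panel and a
# replicate log-probability table with a planted elbow at K = 2.
# Everything downstream (02-06) reads from results/fixtures/.

suppressPackageStartupMessages(library(ssrmine))
seed <- 20260926L
fx <- "results/fixtures"
dir.create(fx, recursive = TRUE, showWarnings = FALSE)

src <- make_ssr_genome(length = 180000, n_loci = 36L, n_chromosomes = 3L,
                       min_gap = 1200L, seed = seed)
write_fasta(src$genome, file.path(fx, "source_genome.fa"))
write_planting_record(src$record, file.path(fx, "source_record.json"))
cat(sprintf("source genome: %d chromosomes, %d planted loci\n",
            length(src$genome), nrow(src$record)))

for (k in 1:2) {
  p <- derive_partner_genome(src, n_inversions = 2L, n_translocations = 1L,
                             segment_markers = 5L, mutation_rate = 0.003,
                             seed = seed + k)
  write_fasta(p$genome, file.path(fx, sprintf("partner%d_genome.fa", k)))
  write_planting_record(list(markers = p$markers, ops = p$ops),
                        file.path(fx, sprintf("partner%d_record.json", k)))
  cat(sprintf("partner %d: %d inversions, %d translocations, mutation rate %.3f\n",
              k, sum(p$ops$op == "inversion"), sum(p$ops$op == "translocation"),
              p$params$mutation_rate))
}

panel <- simulate_genotypes(K = 2L, n_per_pop = 67L, n_loci = 32L,
                            alleles_per_locus = 5L, divergence = 0.2,
                            seed = seed)
write_genotypes(panel$gm, file.path(fx, "panel_genotypes.tsv"))
write_planting_record(as.list(panel$labels), file.path(fx, "panel_labels.json"))
cat(sprintf("genotype panel: %d accessions x %d loci from K = 2 populations\n",
            length(panel$gm$accessions), length(panel$gm$loci)))

runs <- simulate_lnpd(k_range = 1:10, elbow_K = 2L, replicates = 20L,
                      seed = seed)
write.table(runs, file.path(fx, "lnpd_runs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("LnP(D) table: K = 1..10, 20 replicates, planted elbow at K = 2\n")
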