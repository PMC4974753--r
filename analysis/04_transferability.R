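#!/usr/bin/env Rscript
# Electronic PCR of every marker against the two diverged partner genomes
# under the asymmetric mismatch rule (up to 5 mismatches in the 5' window,
# none elsewhere, >= 90 % identity). Single-product markers are the
# cross-species transferable set; the intersection over both partners is
# the three-genome shared set.

suppressPackageStartupMessages(library(ssrmine))
fx <- "results/fixtures"

markers <- read_markers("results/ssr_markers.tsv")
rule <- match_rule()

transfers <- list()
for (k in 1:2) {
  target <- read_fasta(file.path(fx, sprintf("partner%d_genome.fa", k)))
  tt <- classify_transferability(markers, target, rule)
  transfers[[k]] <- tt
  print(tt)
  write_amplicons(tt$amplicons, sprintf("results/amplicons_partner%d.tsv", k))
  write.table(tt$counts, sprintf("results/transfer_partner%d.tsv", k),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

shared3 <- intersect_transfer_sets(transfers[[1L]], transfers[[2L]])
writeLines(shared3, "results/shared_three_genomes.txt")
cat(sprintf("markers single-copy in both partners: %d of %d\n",
            length(shared3), nrow(markers)))

# interval-overlap annotation demo against an arbitrary gene-like track on
# partner 1 (synthetic intervals; stands in for a real gene-model GFF3)
set.seed(1L)
target1 <- read_fasta(file.path(fx, "partner1_genome.fa"))
feats <- do.call(rbind, lapply(names(target1), function(ch) {
  st <- sort(sample.int(nchar(target1[[ch]]) - 2000L, 20L))
  data.frame(seq_id = ch, start = st, end = st + sample(500:2000, 20L, TRUE),
             type = "gene", stringsAsFactors = FALSE)
}))
ann <- annotate_markers(transfers[[1L]]$amplicons, feats,
                        genome_seq_ids = names(target1))
write.table(ann$per_marker, "results/marker_annotation_partner1.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("markers overlapping a synthetic gene interval on partner 1: %d\n",
            ann$n_genic))
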