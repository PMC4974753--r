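test_that("motif class table encodes the per-class length thresholds", {
  cls <- motif_classes()
  expect_equal(cls$min_total_length, c(18L, 18L, 18L, 20L, 24L, 21L, 24L))
  expect_equal(cls$min_repeats, c(9L, 6L, 5L, 4L, 4L, 3L, 3L))
  # min_repeats is the smallest r with r * unit >= min_total_length
  expect_true(all(cls$min_repeats * cls$unit_length >= cls$min_total_length))
  expect_true(all((cls$min_repeats - 1L) * cls$unit_length < cls$min_total_length))
})

test_that("scanning is sharp at every class threshold", {
  expect_equal(nrow(scan_sequence("")), 0L)
  cls <- motif_classes()
  motifs <- c("AT", "AAG", "AAGT", "AACGT", "AACGTT", "AACGTTG", "AACGTTGC")
  for (k in seq_len(nrow(cls))) {
    at <- strrep(motifs[k], cls$min_repeats[k])
    below <- strrep(motifs[k], cls$min_repeats[k] - 1L)
    hit <- scan_sequence(at)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$motif, motifs[k])
    expect_equal(hit$repeat_count, cls$min_repeats[k])
    expect_equal(c(hit$start, hit$end), c(1L, nchar(at)))
    expect_equal(nrow(scan_sequence(below)), 0L)
  }
})

test_that("runs are reported once, under the shortest generating unit", {
  # (AT)10 also reads as (ATAT)5 but only the dinucleotide locus is real
  hit <- scan_sequence(strrep("AT", 10))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_length, 2L)
  # embedded in background
  seq <- paste0(strrep("C", 30), strrep("AT", 10), strrep("G", 30))
  hit <- scan_sequence(seq)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(31L, 50L))
})

test_that("ambiguity codes break runs and invalid characters are rejected", {
  seq <- paste0(strrep("AT", 5), "N", strrep("AT", 5))
  expect_equal(nrow(scan_sequence(seq)), 0L)  # both halves below threshold
  seq2 <- paste0(strrep("AT", 9), "N", strrep("AT", 9))
  hit <- scan_sequence(seq2)
  expect_equal(nrow(hit), 2L)
  expect_true(all(hit$end < 19L | hit$start > 19L))
  expect_error(scan_sequence("ACGTXACGT"), "offset 5")
})

test_that("planted loci are recovered exactly on a 10 kb genome", {
  sim <- make_ssr_genome(length = 10000, n_loci = 25L, seed = 401L)
  hit <- scan_sequence(sim$genome[[1L]], seq_id = "chr1")
  expect_equal(nrow(hit), 25L)
  expect_equal(hit$start, sim$record$start)
  expect_equal(hit$end, sim$record$end)
  expect_equal(hit$motif, sim$record$motif)
  expect_equal(hit$repeat_count, sim$record$repeat_count)
})

test_that("scanner agrees with the brute-force enumerator", {
  set.seed(402)
  for (rep in 1:8) {
    sim <- make_ssr_genome(length = 2000, n_loci = (rep %% 4) + 1L,
                           seed = 500L + rep)
    got <- scan_sequence(sim$genome[[1L]])
    want <- brute_scan(sim$genome[[1L]])
    expect_equal(got[c("start", "end", "motif", "unit_length", "repeat_count")],
                 want)
  }
})

test_that("reverse-complementing a sequence preserves canonical families", {
  sim <- make_ssr_genome(length = 5000, n_loci = 12L, seed = 403L)
  fwd <- scan_sequence(sim$genome[[1L]])
  rev <- scan_sequence(revcomp(sim$genome[[1L]]))
  expect_equal(sort(fwd$canonical_motif), sort(rev$canonical_motif))
  expect_equal(sort(fwd$repeat_count), sort(rev$repeat_count))
})

test_that("canonical_motif picks the smallest rotation over both strands", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("CT"), "AG")
  expect_equal(canonical_motif("GAA"), "AAG")
  # idempotent over random motifs
  set.seed(404)
  for (u in 2:8) {
    m <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE), collapse = "")
    cm <- canonical_motif(m)
    expect_equal(canonical_motif(cm), cm)
    expect_equal(canonical_motif(revcomp(m)), cm)
  }
  expect_error(canonical_motif("ANT"), "invalid motif")
})

test_that("compound merging joins loci iff the gap is within the limit", {
  loci <- rbind(
    scan_sequence(paste0(strrep("AT", 9), strrep("C", 6), strrep("AAG", 6),
                         strrep("T", 200), strrep("AAGT", 6))))
  expect_equal(nrow(loci), 3L)
  merged <- merge_compound(loci, max_interruption = 100L)
  expect_equal(nrow(merged), 2L)
  cmp <- merged[merged$kind == "compound", ]
  expect_equal(c(cmp$start, cmp$end), c(1L, 42L))
  expect_equal(cmp$member_motifs, "AT,AAG")
  expect_true(is.na(cmp$unit_length))
  # far-apart loci pass through untouched
  far <- merge_compound(loci[c(1L, 3L), ], max_interruption = 100L)
  expect_equal(far$kind, c("perfect", "perfect"))
  expect_error(merge_compound(loci, max_interruption = -1), "non-negative")
})

test_that("compound merging matches a brute-force gap check on random layouts", {
  set.seed(405)
  for (rep in 1:10) {
    n <- 6L
    gaps <- sample(c(5L, 50L, 100L, 101L, 150L, 400L), n - 1L, replace = TRUE)
    starts <- integer(n); starts[1L] <- 1L
    len <- 18L
    for (i in 2:n) starts[i] <- starts[i - 1L] + len + gaps[i - 1L]
    loci <- data.frame(seq_id = "c", start = starts, end = starts + len - 1L,
                       motif = "AT", canonical_motif = "AT", unit_length = 2L,
                       repeat_count = 9L, kind = "perfect",
                       member_motifs = NA_character_, stringsAsFactors = FALSE)
    merged <- merge_compound(loci, max_interruption = 100L)
    expect_equal(nrow(merged), 1L + sum(gaps > 100L))
    # order independence
    shuf <- merge_compound(loci[sample(n), ], max_interruption = 100L)
    expect_equal(merged, shuf)
  }
})

test_that("catalog summaries reproduce brute-force tallies", {
  sim <- make_ssr_genome(length = 40000, n_loci = 40L, n_chromosomes = 2L,
                         seed = 406L)
  catalog <- scan_genome(sim$genome)
  s <- summarize_catalog(catalog)
  expect_equal(s$total, 40L)
  expect_equal(sum(s$per_class$frequency_pct), 100)
  expect_equal(s$density, 1e6 * 40 / sum(nchar(sim$genome)))
  # independent tally from the planting record
  cls <- motif_classes()
  want <- table(factor(sim$record$class_name, levels = cls$class_name))
  for (cn in s$per_class$class_name) {
    expect_equal(s$per_class$n[s$per_class$class_name == cn],
                 as.numeric(want[[cn]]))
  }
  expect_equal(sum(s$per_chromosome$n), 40L)
  # one-locus catalog is 100 % of its class
  one <- summarize_catalog(catalog[1L, ])
  expect_equal(one$per_class$frequency_pct, 100)
  # empty catalog returns an empty summary, not an error
  empty <- summarize_catalog(catalog[0L, ])
  expect_equal(empty$total, 0L)
  expect_equal(nrow(empty$per_class), 0L)
})

test_that("marker ids follow the prefix + zero-padded ordinal convention", {
  sim <- make_ssr_genome(length = 5000, n_loci = 3L, seed = 407L)
  catalog <- scan_genome(sim$genome, prefix = "XySSR")
  expect_equal(catalog$marker_id, c("XySSR00001", "XySSR00002", "XySSR00003"))
})
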