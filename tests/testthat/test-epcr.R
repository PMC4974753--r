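make_target <- function(...) {
  parts <- list(...)
  setNames(vapply(parts, paste0, "", collapse = ""), names(parts))
}

test_that("binding sites honour the asymmetric mismatch rule", {
  set.seed(420)
  primer <- random_dna(20)
  bg1 <- random_dna(150); bg2 <- random_dna(150)
  target <- c(chr = paste0(bg1, primer, bg2))

  hit <- find_binding_sites(primer, target)
  exact <- hit[hit$start == 151L & hit$strand == "+", ]
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$mismatches, 0L)

  mutate_at <- function(p, pos) {
    ch <- strsplit(p, "")[[1L]]
    for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1L]
    paste(ch, collapse = "")
  }
  # a single mismatch at the 3'-terminal base kills the site
  t2 <- c(chr = paste0(bg1, mutate_at(primer, 20L), bg2))
  h2 <- find_binding_sites(primer, t2)
  expect_false(any(h2$start == 151L & h2$strand == "+"))
  # 2 mismatches at 5' positions 1-2: identity 18/20 = 0.90, reported
  t3 <- c(chr = paste0(bg1, mutate_at(primer, 1:2), bg2))
  h3 <- find_binding_sites(primer, t3)
  site <- h3[h3$start == 151L & h3$strand == "+", ]
  expect_equal(nrow(site), 1L)
  expect_equal(site$mismatches, 2L)
  # 3 mismatches at positions 1-3: identity 0.85 < 0.90, rejected even
  # though the 5' window would allow up to 5
  t4 <- c(chr = paste0(bg1, mutate_at(primer, 1:3), bg2))
  h4 <- find_binding_sites(primer, t4)
  expect_false(any(h4$start == 151L & h4$strand == "+"))
  # a mismatch just outside the window (position 6) is rejected
  t5 <- c(chr = paste0(bg1, mutate_at(primer, 6L), bg2))
  h5 <- find_binding_sites(primer, t5)
  expect_false(any(h5$start == 151L & h5$strand == "+"))

  expect_error(find_binding_sites("ACGTACG", target), "15-40")
  expect_error(find_binding_sites(primer, target,
                                  match_rule(five_prime_window = 16L)),
               "five_prime_window")
})

test_that("sites and amplicons agree with brute-force scanners", {
  set.seed(421)
  sim <- make_ssr_genome(length = 30000, n_loci = 8L, min_gap = 700L, seed = 422L)
  mk <- design_markers(sim$genome, scan_genome(sim$genome))
  rule <- match_rule()
  for (i in seq_len(nrow(mk))) {
    for (p in c(mk$fwd_seq[i], mk$rev_seq[i])) {
      expect_equal(find_binding_sites(p, sim$genome, rule),
                   brute_sites(p, sim$genome, rule))
    }
    got <- amplify(mk[i, ], sim$genome, rule)
    want <- brute_amplify(mk[i, ], sim$genome, rule)
    expect_equal(got[c("seq_id", "start", "end")], want)
  }
})

test_that("convergent orientation is required and duplicated sites multiply products", {
  set.seed(423)
  fwd <- random_dna(20); rev <- random_dna(20)
  marker <- data.frame(marker_id = "M1", fwd_seq = fwd, rev_seq = rev,
                       stringsAsFactors = FALSE)
  spacer <- random_dna(160)
  # fwd ... revcomp(rev): one product
  t1 <- make_target(chr = c(random_dna(100), fwd, spacer, revcomp(rev),
                            random_dna(100)))
  expect_equal(nrow(amplify(marker, t1)), 1L)
  # reverse site upstream of the forward site: no product
  t2 <- make_target(chr = c(random_dna(100), revcomp(rev), spacer, fwd,
                            random_dna(100)))
  expect_equal(nrow(amplify(marker, t2)), 0L)
  # forward site duplicated upstream of one reverse site: two products
  t3 <- make_target(chr = c(random_dna(100), fwd, random_dna(120), fwd,
                            spacer, revcomp(rev), random_dna(100)))
  got <- amplify(marker, t3)
  expect_equal(nrow(got), 2L)
  expect_equal(got[c("seq_id", "start", "end")], brute_amplify(marker, t3))
})

test_that("transfer classification matches planted copy numbers", {
  set.seed(424)
  sim <- make_ssr_genome(length = 40000, n_loci = 12L, min_gap = 700L, seed = 425L)
  mk <- design_markers(sim$genome, scan_genome(sim$genome))
  mk <- mk[seq_len(12L), ]
  # synthetic target: copy the amplicon region of 10 markers once and of 2
  # markers twice, in random order with random spacers
  region <- function(i) substr(sim$genome[[1L]],
                               mk$fwd_start[i] - 5L, mk$rev_end[i] + 5L)
  once <- 1:10
  twice <- 11:12
  pieces <- c(lapply(once, region), lapply(rep(twice, 2L), region))
  pieces <- pieces[sample(length(pieces))]
  target <- c(T1 = paste(unlist(lapply(pieces, function(p)
    c(p, random_dna(300)))), collapse = ""))
  # cap the product size below the inter-copy spacing so only within-copy
  # pairings count
  tt <- classify_transferability(mk, target, product_bounds = c(50L, 400L))
  expect_setequal(tt$single_copy, mk$marker_id[once])
  expect_setequal(tt$multi_copy, mk$marker_id[twice])
  expect_equal(tt$counts$n_products[match(mk$marker_id[twice], tt$counts$marker_id)],
               c(2L, 2L))
  # markers absent from an unrelated target have no product
  t0 <- c(T2 = random_dna(5000))
  tt0 <- classify_transferability(mk, t0)
  expect_equal(length(tt0$no_product), 12L)
})

test_that("reverse-complementing the whole target leaves product counts unchanged", {
  sim <- make_ssr_genome(length = 30000, n_loci = 8L, min_gap = 700L, seed = 426L)
  mk <- design_markers(sim$genome, scan_genome(sim$genome))
  tt1 <- classify_transferability(mk, sim$genome)
  tt2 <- classify_transferability(mk, setNames(revcomp(sim$genome[[1L]]), "chr1"))
  expect_equal(tt1$counts$n_products, tt2$counts$n_products)
})

test_that("single-copy intersection across targets is plain set algebra", {
  fake <- function(single, universe) {
    structure(list(counts = data.frame(marker_id = universe,
                                       n_products = as.integer(universe %in% single),
                                       stringsAsFactors = FALSE),
                   single_copy = single, multi_copy = character(),
                   no_product = setdiff(universe, single), amplicons = NULL),
              class = "transfer_table")
  }
  u <- c("A", "B", "C", "D")
  expect_setequal(intersect_transfer_sets(fake(c("A", "B", "C"), u),
                                          fake(c("B", "C", "D"), u)),
                  c("B", "C"))
  expect_length(intersect_transfer_sets(fake(character(), u), fake(u, u)), 0L)
  expect_error(intersect_transfer_sets(fake("A", c("A", "B")),
                                       fake("X", c("X", "Y"))),
               "disjoint")
})

test_that("feature annotation matches a brute-force overlap check", {
  amp <- data.frame(marker_id = c("M1", "M2", "M3"), seq_id = "chr1",
                    start = c(100L, 300L, 500L), end = c(199L, 399L, 599L),
                    stringsAsFactors = FALSE)
  feats <- data.frame(seq_id = "chr1", start = c(150L, 400L),
                      end = c(160L, 450L), type = "CDS",
                      stringsAsFactors = FALSE)
  ann <- annotate_markers(amp, feats)
  # M1 overlaps a CDS; M2 ends 1 bp before a CDS start; M3 is far away
  expect_equal(ann$per_marker$genic, c(TRUE, FALSE, FALSE))
  expect_equal(ann$n_genic, 1L)
  expect_warning(
    annotate_markers(amp, rbind(feats, data.frame(seq_id = "chrX", start = 1L,
                                                  end = 10L, type = "CDS")),
                     genome_seq_ids = "chr1"),
    "chrX")
  # random amplicons vs random intervals against an O(n*m) loop
  set.seed(427)
  ra <- data.frame(marker_id = paste0("M", 1:40), seq_id = "c",
                   start = sample(1:5000, 40), stringsAsFactors = FALSE)
  ra$end <- ra$start + sample(50:300, 40, replace = TRUE)
  rf <- data.frame(seq_id = "c", start = sample(1:5000, 25),
                   stringsAsFactors = FALSE)
  rf$end <- rf$start + sample(20:400, 25, replace = TRUE)
  ann2 <- annotate_markers(ra, rf)
  want <- vapply(seq_len(nrow(ra)), function(i) {
    any(ra$start[i] <= rf$end & ra$end[i] >= rf$start)
  }, TRUE)
  expect_equal(ann2$per_marker$genic[match(ra$marker_id, ann2$per_marker$marker_id)],
               want)
})
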