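gm_from_calls <- function(calls) {
  # calls: list per locus of character vector "a/b" per accession
  n <- length(calls[[1L]])
  a1 <- sapply(calls, function(x) sub("/.*", "", x))
  a2 <- sapply(calls, function(x) sub(".*/", "", x))
  a1[a1 == "?"] <- NA; a2[a2 == "?"] <- NA
  genotype_matrix(matrix(a1, nrow = n), matrix(a2, nrow = n))
}

test_that("allele frequencies count alleles over non-missing genotypes", {
  gm <- gm_from_calls(list(c("A/A", "A/B")))
  expect_equal(allele_frequencies(gm)[[1L]], c(A = 0.75, B = 0.25))
  gm2 <- gm_from_calls(list(c("A/A", "A/A", "A/A")))
  expect_equal(allele_frequencies(gm2)[[1L]], c(A = 1))
  gm3 <- gm_from_calls(list(c("A/B", "?/?", "B/B")))
  expect_equal(allele_frequencies(gm3)[[1L]], c(A = 0.25, B = 0.75))
  gm4 <- gm_from_calls(list(c("?/?", "?/?")))
  expect_error(allele_frequencies(gm4), "locus")
})

test_that("locus statistics match closed forms", {
  mono <- locus_stats(gm_from_calls(list(c("A/A", "A/A"))))
  expect_equal(mono$Na, 1L)
  expect_equal(mono$Ne, 1)
  expect_equal(mono$He, 0)
  expect_equal(mono$I, 0)
  expect_equal(mono$Ho, 0)
  expect_equal(mono$PIC, 0)

  # two alleles at 0.5/0.5 (and Ho = 1 since both accessions are A/B)
  even <- locus_stats(gm_from_calls(list(c("A/B", "B/A"))))
  expect_equal(even$Ne, 2)
  expect_equal(even$He, 0.5)
  expect_equal(even$I, log(2))
  expect_equal(even$PIC, 0.375)  # Botstein
  expect_equal(even$Ho, 1)
  # selectable variants
  gm <- gm_from_calls(list(c("A/B", "B/A")))
  expect_equal(locus_stats(gm, pic = "he")$PIC, 0.5)
  expect_equal(locus_stats(gm, pic = "legacy")$PIC, 0.5)
})

test_that("locus statistics match a direct-summation oracle on random data", {
  set.seed(430)
  for (rep in 1:10) {
    sim <- simulate_genotypes(K = 1L, n_per_pop = 30L, n_loci = 5L,
                              alleles_per_locus = sample(2:6, 1L),
                              divergence = 1, seed = 430L + rep)
    st <- locus_stats(sim$gm)
    fr <- allele_frequencies(sim$gm)
    for (j in seq_along(sim$gm$loci)) {
      p <- fr[[j]]
      # independent direct sums
      expect_equal(st$Na[j], length(p))
      expect_equal(st$Ne[j], 1 / sum(p * p), tolerance = 1e-12)
      expect_equal(st$He[j], 1 - sum(p * p), tolerance = 1e-12)
      expect_equal(st$I[j], -sum(p * log(p)), tolerance = 1e-12)
      pic <- 1 - sum(p^2)
      for (a in seq_along(p)) for (b in seq_along(p)) {
        if (a < b) pic <- pic - 2 * p[[a]]^2 * p[[b]]^2
      }
      expect_equal(st$PIC[j], pic, tolerance = 1e-12)
      het <- mean(sim$gm$allele1[, j] != sim$gm$allele2[, j])
      expect_equal(st$Ho[j], het)
      # invariants
      expect_true(st$Ne[j] >= 1 && st$Ne[j] <= st$Na[j] + 1e-12)
      expect_true(st$PIC[j] <= st$He[j] + 1e-12)
    }
  }
})

test_that("statistics are invariant to allele relabeling and accession order", {
  sim <- simulate_genotypes(K = 1L, n_per_pop = 20L, n_loci = 4L, seed = 431L)
  st <- locus_stats(sim$gm)
  # relabel alleles with arbitrary new names
  relab <- function(m) matrix(paste0("z", m), nrow = nrow(m),
                              dimnames = dimnames(m))
  gm2 <- genotype_matrix(relab(sim$gm$allele1), relab(sim$gm$allele2))
  expect_equal(locus_stats(gm2)[-1L], st[-1L])
  # reorder accessions
  ord <- sample(length(sim$gm$accessions))
  gm3 <- genotype_matrix(sim$gm$allele1[ord, ], sim$gm$allele2[ord, ])
  expect_equal(locus_stats(gm3)[-1L], st[-1L])
})

test_that("He, I and PIC are maximal at uniform allele frequencies", {
  set.seed(432)
  stat_of <- function(p) {
    c(he = 1 - sum(p^2), i = -sum(p * log(p)),
      pic = 1 - sum(p^2) - (sum(p^2)^2 - sum(p^4)))
  }
  for (k in 2:6) {
    uni <- stat_of(rep(1 / k, k))
    for (rep in 1:20) {
      g <- rgamma(k, 1); p <- g / sum(g)
      expect_true(all(stat_of(p) <= uni + 1e-12))
    }
  }
})

test_that("allele-sharing distances follow the shared-allele count", {
  gm <- gm_from_calls(list(c("A/B", "A/B", "C/D", "A/C"),
                           c("E/E", "E/E", "F/G", "E/F")))
  d <- distance_matrix(gm)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d[1L, 2L], 0)            # identical multilocus genotypes
  expect_equal(d[1L, 3L], 1)            # fully disjoint alleles
  expect_equal(d[1L, 4L], 0.5)          # one shared allele of two, both loci
  expect_true(isSymmetric(d))
  # vectorized distances equal the scalar multiset-intersection oracle
  set.seed(433)
  sim <- simulate_genotypes(K = 2L, n_per_pop = 8L, n_loci = 6L,
                            missing_rate = 0.1, seed = 433L)
  dv <- distance_matrix(sim$gm)
  a1 <- sim$gm$allele1; a2 <- sim$gm$allele2
  for (i in 1:5) for (j in (i + 1L):6L) {
    both <- which(!is.na(a1[i, ]) & !is.na(a1[j, ]))
    sh <- vapply(both, function(l) {
      oracle_shared_alleles(a1[i, l], a2[i, l], a1[j, l], a2[j, l])
    }, 0L)
    expect_equal(dv[i, j], 1 - mean(sh) / 2)
  }
  # a pair with no jointly scored locus is an error
  gm_bad <- genotype_matrix(matrix(c("A", NA, NA, "B"), 2L, 2L),
                            matrix(c("A", NA, NA, "B"), 2L, 2L))
  expect_error(distance_matrix(gm_bad), "no scored locus")
})

test_that("UPGMA reproduces the textbook case and breaks ties deterministically", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(ape::write.tree(tr), "((A:1,B:1):2,C:3);")
  # all-equal distances: deterministic and ultrametric with equal tip depths
  d4 <- matrix(4, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0
  t1 <- upgma(d4); t2 <- upgma(d4)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  depths <- ape::node.depth.edgelength(t1)[seq_len(ape::Ntip(t1))]
  expect_true(max(depths) - min(depths) < 1e-9)
  # asymmetric input is rejected
  bad <- d; bad[1L, 2L] <- 3
  expect_error(upgma(bad), "symmetric")
})

test_that("UPGMA is ultrametric and exact on ultrametric inputs", {
  set.seed(434)
  for (rep in 1:5) {
    # a random coalescent tree is ultrametric; its cophenetic matrix must be
    # reproduced exactly
    ref <- ape::rcoal(8L)
    d <- ape::cophenetic.phylo(ref)
    tr <- upgma(d)
    got <- ape::cophenetic.phylo(tr)
    expect_equal(got[rownames(d), colnames(d)], d, tolerance = 1e-9)
  }
  # against hclust average linkage on a random (non-ultrametric) matrix
  x <- matrix(rnorm(60), 10L)
  rownames(x) <- paste0("s", 1:10)
  d <- dist(x)
  tr <- upgma(as.matrix(d))
  hc <- stats::hclust(d, method = "average")
  got <- ape::cophenetic.phylo(tr)
  want <- ape::cophenetic.phylo(ape::as.phylo(hc))
  expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-9)
})

test_that("strongly diverged populations split at the root with pure clades", {
  sim <- simulate_genotypes(K = 2L, n_per_pop = 20L, n_loci = 20L,
                            divergence = 0.1, seed = 435L)
  tr <- upgma(distance_matrix(sim$gm))
  expect_equal(split_purity(dendrogram_top_split(tr), sim$labels), 1)
})

test_that("Evanno delta-K finds planted elbows and is zero for linear tables", {
  # exactly linear mean response: zero curvature everywhere
  runs <- expand.grid(run = 1:3, K = 1:6)
  runs$LnPD <- -1000 + 50 * runs$K + rep(c(-1, 0, 1), 6L)
  dk <- evanno_delta_k(runs)
  expect_equal(dk$table$delta_k[2:5], rep(0, 4), tolerance = 1e-9)
  # planted elbow with replicate noise
  dk2 <- evanno_delta_k(simulate_lnpd(elbow_K = 3L, seed = 436L))
  expect_equal(dk2$best_k, 3L)
  # zero-noise: infinite sentinel exactly at the elbow
  expect_warning(
    dk3 <- evanno_delta_k(simulate_lnpd(elbow_K = 4L, noise_sd = 0, seed = 437L)),
    "Inf")
  expect_true(is.infinite(dk3$table$delta_k[dk3$table$K == 4L]))
  expect_equal(dk3$best_k, 4L)
  # input validation
  expect_error(evanno_delta_k(runs[runs$K <= 2L, ]), "consecutive")
  expect_error(evanno_delta_k(runs[runs$run == 1L, ]), "replicates")
})

test_that("doubling replicate noise halves delta-K in expectation", {
  mean_dk <- function(sd) {
    mean(vapply(1:60, function(s) {
      dk <- evanno_delta_k(simulate_lnpd(elbow_K = 2L, noise_sd = sd,
                                         seed = 5000L + s))
      dk$table$delta_k[dk$table$K == 2L]
    }, 0))
  }
  m1 <- mean_dk(20)
  m2 <- mean_dk(40)
  expect_equal(m1 / m2, 2, tolerance = 0.25)
})
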