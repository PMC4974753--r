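#' Construct a codominant genotype matrix
#'
#' Holds unordered diploid allele pairs per (accession, locus). Allele
#' labels are arbitrary (typically product-size labels); missing calls are
#' `NA` in both allele slots and are never imputed.
#'
#' @param allele1,allele2 character or numeric matrices, accessions x loci;
#'   a missing call has `NA` in both.
#' @param accessions,loci row/column names (taken from `allele1` when
#'   `NULL`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(allele1, allele2, accessions = NULL, loci = NULL) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  stopifnot(identical(dim(allele1), dim(allele2)))
  if (any(is.na(allele1) != is.na(allele2))) {
    stop("half-missing genotype calls are not allowed")
  }
  if (is.null(accessions)) accessions <- rownames(allele1)
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(nrow(allele1)))
  if (is.null(loci)) loci <- colnames(allele1)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(allele1)))
  mode(allele1) <- "character"; mode(allele2) <- "character"
  dimnames(allele1) <- dimnames(allele2) <- list(accessions, loci)
  structure(list(allele1 = allele1, allele2 = allele2,
                 accessions = accessions, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%.1f%% missing)\n",
              length(x$accessions), length(x$loci),
              100 * mean(is.na(x$allele1))))
  invisible(x)
}

#' Per-locus allele frequencies
#'
#' Allele frequency = allele count / (2 x non-missing genotypes); missing
#' calls are excluded from the denominator (pairwise deletion).
#'
#' @param gm a [genotype_matrix()].
#' @return named list (per locus) of named frequency vectors, each summing
#'   to 1.
#' @export
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- lapply(seq_along(gm$loci), function(j) {
    a <- c(gm$allele1[, j], gm$allele2[, j])
    a <- a[!is.na(a)]
    if (length(a) == 0L) {
      stop("all calls missing at locus ", gm$loci[j])
    }
    tab <- table(a)
    setNames(as.numeric(tab) / length(a), names(tab))
  })
  names(out) <- gm$loci
  out
}

#' Per-locus diversity statistics
#'
#' Computes, per locus: observed allele number `Na`, effective allele number
#' `Ne = 1 / sum(p^2)`, observed heterozygosity `Ho` (heterozygous /
#' non-missing genotypes), expected heterozygosity `He = 1 - sum(p^2)`,
#' Shannon's information index `I = -sum(p log p)` and the polymorphic
#' information content `PIC`. The default PIC is the Botstein (1980) form
#' `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`; variant `"he"` returns
#' `1 - sum(p^2)` and variant `"legacy"` the raw `sum(p^2)` (expected
#' homozygosity, kept only because some older reports print this form).
#'
#' @param gm a [genotype_matrix()].
#' @param freqs optional precomputed [allele_frequencies()].
#' @param pic one of `"botstein"`, `"he"`, `"legacy"`.
#' @return `data.frame` with one row per locus: `locus`, `Na`, `Ne`, `Ho`,
#'   `He`, `I`, `PIC`.
#' @export
locus_stats <- function(gm, freqs = allele_frequencies(gm),
                        pic = c("botstein", "he", "legacy")) {
  pic <- match.arg(pic)
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- lapply(seq_along(gm$loci), function(j) {
    p <- freqs[[gm$loci[j]]]
    sp2 <- sum(p^2)
    a1 <- gm$allele1[, j]; a2 <- gm$allele2[, j]
    scored <- !is.na(a1)
    ho <- if (any(scored)) mean(a1[scored] != a2[scored]) else NA_real_
    pic_val <- switch(pic,
      botstein = {
        p2 <- p^2
        cross <- (sum(p2)^2 - sum(p2^2)) / 2   # sum_{i<j} p_i^2 p_j^2
        1 - sp2 - 2 * cross
      },
      he = 1 - sp2,
      legacy = sp2)
    data.frame(locus = gm$loci[j], Na = length(p), Ne = 1 / sp2, Ho = ho,
               He = 1 - sp2, I = -sum(p * log(p)), PIC = pic_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele-sharing distance matrix
#'
#' `d(a, b) = 1 - mean_l(shared alleles at locus l / 2)` over loci scored in
#' both accessions (pairwise deletion). 0 for identical multilocus
#' genotypes, 1 for fully disjoint ones.
#'
#' @param gm a [genotype_matrix()] with at least two accessions.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$accessions) >= 2L)
  n <- length(gm$accessions)
  d <- matrix(0, n, n, dimnames = list(gm$accessions, gm$accessions))
  a1 <- gm$allele1; a2 <- gm$allele2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(both)) {
        stop(sprintf("accessions %s and %s share no scored locus",
                     gm$accessions[i], gm$accessions[j]))
      }
      # multiset intersection of two diploid genotypes: 2 iff the unordered
      # pairs are equal, so the max of the straight and crossed matchings
      # equals min(count_1, count_2) summed over allele types
      straight <- (a1[i, both] == a1[j, both]) + (a2[i, both] == a2[j, both])
      crossed <- (a1[i, both] == a2[j, both]) + (a2[i, both] == a1[j, both])
      d[i, j] <- d[j, i] <- 1 - mean(pmax(straight, crossed)) / 2
    }
  }
  d
}

#' UPGMA dendrogram
#'
#' Agglomerative clustering with unweighted arithmetic-mean linkage: the two
#' closest clusters are joined at height `d/2`, and distances to the merged
#' cluster are leaf-count-weighted means, so every cluster-to-cluster
#' distance stays the arithmetic mean over its leaf pairs. Ties are broken
#' deterministically by the lexicographic order of the clusters' sorted
#' leaf-label sets. The result is rooted and ultrametric.
#'
#' @param d symmetric non-negative distance matrix (zero diagonal) with
#'   dimnames, or a [stats::dist].
#' @return an [ape] `phylo` tree.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (!isSymmetric(unname(m), tol = 1e-12) || any(diag(m) != 0) || any(m < 0)) {
    stop("distance matrix must be symmetric and non-negative with zero diagonal")
  }
  n <- nrow(m)
  stopifnot(n >= 2L)
  labels <- rownames(m)
  newick <- labels
  height <- rep(0, n)
  key <- labels                     # sorted-leaf-set key per active cluster
  size <- rep(1L, n)
  active <- rep(TRUE, n)

  fmt <- function(x) formatC(x, format = "g", digits = 15)
  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- m[idx, idx, drop = FALSE]
    off <- sub + diag(Inf, length(idx))
    dmin <- min(off)
    cand <- which(off == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest (key_i, key_j) pair
    pair_keys <- t(apply(cand, 1L, function(rc) sort(c(key[idx[rc[1L]]], key[idx[rc[2L]]]))))
    pick <- order(pair_keys[, 1L], pair_keys[, 2L])[1L]
    i <- idx[cand[pick, 1L]]; j <- idx[cand[pick, 2L]]
    if (key[j] < key[i]) { tmp <- i; i <- j; j <- tmp }
    h <- dmin / 2
    newick_i <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(h - height[i]),
                        newick[j], fmt(h - height[j]))
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      dn <- (size[i] * m[i, others] + size[j] * m[j, others]) / (size[i] + size[j])
      m[i, others] <- dn
      m[others, i] <- dn
    }
    newick[i] <- newick_i
    height[i] <- h
    size[i] <- size[i] + size[j]
    key[i] <- paste(sort(c(strsplit(key[i], "\r", fixed = TRUE)[[1L]],
                           strsplit(key[j], "\r", fixed = TRUE)[[1L]])),
                    collapse = "\r")
    active[j] <- FALSE
  }
  root <- which(active)
  ape::read.tree(text = paste0(newick[root], ";"))
}

#' Leaf sets of the two clades under the root
#'
#' @param tree a rooted binary `phylo` tree (e.g. from [upgma()]).
#' @return list of two character vectors of tip labels.
#' @export
dendrogram_top_split <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  lapply(kids, function(k) {
    if (k <= ape::Ntip(tree)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
}

#' Purity of a two-way split against reference labels
#'
#' Fraction of tips whose reference label matches the majority label of
#' their side of the split, maximized over the two label-to-side
#' assignments.
#'
#' @param split list of two character vectors of tip names.
#' @param labels named vector of reference labels (two groups).
#' @return purity in `[0, 1]`.
#' @export
split_purity <- function(split, labels) {
  stopifnot(length(split) == 2L)
  groups <- unique(labels)
  stopifnot(length(groups) == 2L)
  n <- sum(lengths(split))
  match1 <- sum(labels[split[[1L]]] == groups[1L]) +
    sum(labels[split[[2L]]] == groups[2L])
  max(match1, n - match1) / n
}

#' Evanno delta-K from replicate log-probability tables
#'
#' For STRUCTURE-style runs over a contiguous range of K with replicates,
#' computes per interior K the absolute second difference of the replicate
#' mean log probability, `|L(K+1) - 2 L(K) + L(K-1)|`, divided by the
#' standard deviation of the replicates at K; the argmax over interior K
#' estimates the number of populations. Second differences use per-K
#' replicate means because replicates are not paired across K. A zero
#' replicate standard deviation yields an infinite delta-K with a warning.
#'
#' @param runs `data.frame` with columns `K`, `run`, `LnPD`; at least three
#'   consecutive K values with at least two replicates each.
#' @return list of class `deltak_result`: `table` (`K`, `mean_lnpd`,
#'   `sd_lnpd`, `second_diff`, `delta_k`) and `best_k` (interior argmax;
#'   smallest K on ties).
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "run", "LnPD") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L || !all(diff(ks) == 1L)) {
    stop("need at least 3 consecutive K values")
  }
  reps <- table(runs$K)
  if (any(reps < 2L)) stop("need at least 2 replicates per K")
  mu <- vapply(ks, function(k) mean(runs$LnPD[runs$K == k]), 0)
  sdv <- vapply(ks, function(k) stats::sd(runs$LnPD[runs$K == k]), 0)
  nk <- length(ks)
  second <- rep(NA_real_, nk)
  second[2:(nk - 1L)] <- abs(mu[3:nk] - 2 * mu[2:(nk - 1L)] + mu[1:(nk - 2L)])
  if (any(sdv[2:(nk - 1L)] == 0)) {
    warning("zero replicate standard deviation at some K; delta-K reported as Inf")
  }
  delta <- second / sdv
  delta[!is.na(second) & second == 0] <- 0  # no curvature means no signal even at sd 0
  tab <- data.frame(K = ks, mean_lnpd = mu, sd_lnpd = sdv,
                    second_diff = second, delta_k = delta)
  interior <- 2:(nk - 1L)
  best <- interior[which.max(delta[interior])]
  structure(list(table = tab, best_k = ks[best]), class = "deltak_result")
}

#' @export
print.deltak_result <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("best K (max delta-K over interior K): %d\n", x$best_k))
  invisible(x)
}
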