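#' Primer-design constraints
#'
#' Constraint set for the simplified primer picker: amplicons of 100--300 bp,
#' primer length 18-20-24 (min-opt-max), Tm 50-55-60 degrees C, GC fraction
#' 0.20--0.80, and rejection of primers containing a perfect
#' self-complementary stretch of 8 bp or more.
#'
#' @param product_size_range integer length-2, amplicon bounds in bp.
#' @param primer_length,tm numeric length-3 `(min, opt, max)` triples.
#' @param gc_range numeric length-2 fractional GC bounds.
#' @param self_dimer_max longest tolerated perfect self-complementary
#'   stretch, bp (stretches of this length or more are rejected).
#' @return a list of class `primer_constraints`.
#' @export
primer_constraints <- function(product_size_range = c(100L, 300L),
                               primer_length = c(18L, 20L, 24L),
                               tm = c(50, 55, 60),
                               gc_range = c(0.20, 0.80),
                               self_dimer_max = 8L) {
  stopifnot(length(product_size_range) == 2L,
            product_size_range[1L] <= product_size_range[2L],
            length(primer_length) == 3L, !is.unsorted(primer_length),
            length(tm) == 3L, !is.unsorted(tm),
            length(gc_range) == 2L, gc_range[1L] <= gc_range[2L])
  structure(list(product_size_range = as.integer(product_size_range),
                 primer_length = as.integer(primer_length),
                 tm = as.numeric(tm), gc_range = as.numeric(gc_range),
                 self_dimer_max = as.integer(self_dimer_max)),
            class = "primer_constraints")
}

gc_fraction <- function(x) {
  vapply(x, function(p) {
    n <- nchar(p)
    if (n == 0L) return(NA_real_)
    (nchar(gsub("[^GCgc]", "", p))) / n
  }, 0, USE.NAMES = FALSE)
}

has_self_dimer <- function(primer, k) {
  n <- nchar(primer)
  if (n < k) return(FALSE)
  subs <- substring(primer, 1:(n - k + 1L), k:n)
  any(revcomp(subs) %in% subs)
}

# candidate primers on one flank: all (start, len) windows, annotated with
# sequence, Tm, GC, and the Tm/length penalties used for ranking
primer_candidates <- function(seq, lo, hi, constraints, from_plus_strand) {
  lens <- constraints$primer_length[1L]:constraints$primer_length[3L]
  cand <- do.call(rbind, lapply(lens, function(L) {
    if (hi - L + 1L < lo) return(NULL)
    starts <- seq.int(lo, hi - L + 1L)
    data.frame(start = starts, end = starts + L - 1L, len = L)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand$seq <- substring(seq, cand$start, cand$end)
  if (!from_plus_strand) cand$seq <- revcomp(cand$seq)
  keep <- !grepl("[^ACGT]", cand$seq)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$gc <- gc_fraction(cand$seq)
  cand <- cand[cand$gc >= constraints$gc_range[1L] &
               cand$gc <= constraints$gc_range[2L], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$tm <- melting_temperature(cand$seq)
  cand <- cand[cand$tm >= constraints$tm[1L] & cand$tm <= constraints$tm[3L], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  dimer <- vapply(cand$seq, has_self_dimer, TRUE, k = constraints$self_dimer_max)
  cand <- cand[!dimer, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$tm_pen <- abs(cand$tm - constraints$tm[2L])
  cand$len_pen <- abs(cand$len - constraints$primer_length[2L])
  cand
}

#' Design a primer pair for one SSR locus
#'
#' Simplified primer picker: both primers lie wholly outside the repeat
#' array, the amplicon contains the full array, and the pair satisfies the
#' product-size, length, Tm, GC and self-dimer constraints. Among all
#' feasible pairs the deterministic best is returned: smallest summed
#' `|Tm - opt|`, then smallest summed `|length - opt|`, then leftmost
#' (forward start, then reverse end). Returns `NULL` when the flanks are too
#' short or no pair satisfies the constraints.
#'
#' @param genome genome as accepted by [scan_genome()].
#' @param locus one-row SSR locus `data.frame` (needs `seq_id`, `start`,
#'   `end`; `marker_id`/`motif` are carried through when present).
#' @param constraints a [primer_constraints()] object.
#' @return one-row `data.frame` with `marker_id`, `seq_id`, `ssr_start`,
#'   `ssr_end`, `motif`, `fwd_seq`, `rev_seq` (5'->3' on the minus strand),
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (plus-strand
#'   coordinates), `expected_product_bp`, `fwd_tm`, `rev_tm`; or `NULL`.
#' @export
design_marker <- function(genome, locus, constraints = primer_constraints()) {
  seqs <- as_named_sequences(genome)
  sid <- locus$seq_id[1L]
  if (!sid %in% names(seqs)) stop("locus seq_id not in genome: ", sid)
  seq <- seqs[[sid]]
  n <- nchar(seq)
  s <- locus$start[1L]; e <- locus$end[1L]
  stopifnot(s >= 1L, e <= n, s <= e)
  pmax_ <- constraints$product_size_range[2L]
  plen_min <- constraints$primer_length[1L]

  left_lo <- max(1L, s - pmax_ + 1L); left_hi <- s - 1L
  right_lo <- e + 1L; right_hi <- min(n, e + pmax_ - 1L)
  if (left_hi - left_lo + 1L < plen_min || right_hi - right_lo + 1L < plen_min) {
    return(NULL)  # insufficient flank
  }
  fwd <- primer_candidates(seq, left_lo, left_hi, constraints, TRUE)
  rev <- primer_candidates(seq, right_lo, right_hi, constraints, FALSE)
  if (is.null(fwd) || is.null(rev)) return(NULL)

  # branch-and-bound over forward candidates ordered by Tm penalty
  fwd <- fwd[order(fwd$tm_pen, fwd$len_pen, fwd$start), , drop = FALSE]
  min_rev_tm_pen <- min(rev$tm_pen)
  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf)
  pmin_ <- constraints$product_size_range[1L]
  for (i in seq_len(nrow(fwd))) {
    if (fwd$tm_pen[i] + min_rev_tm_pen > best_key[1L]) break
    prod_len <- rev$end - fwd$start[i] + 1L
    ok <- which(prod_len >= pmin_ & prod_len <= pmax_)
    if (!length(ok)) next
    key1 <- fwd$tm_pen[i] + rev$tm_pen[ok]
    key2 <- fwd$len_pen[i] + rev$len_pen[ok]
    ord <- order(key1, key2, rev$end[ok])
    j <- ok[ord[1L]]
    cand_key <- c(key1[ord[1L]], key2[ord[1L]], fwd$start[i], rev$end[j])
    if (compare_keys(cand_key, best_key) < 0) {
      best_key <- cand_key
      best <- list(f = fwd[i, ], r = rev[j, ])
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(
    marker_id = if ("marker_id" %in% names(locus)) locus$marker_id[1L] else NA_character_,
    seq_id = sid, ssr_start = s, ssr_end = e,
    motif = if ("motif" %in% names(locus)) locus$motif[1L] else NA_character_,
    fwd_seq = best$f$seq, rev_seq = best$r$seq,
    fwd_start = best$f$start, fwd_end = best$f$end,
    rev_start = best$r$start, rev_end = best$r$end,
    expected_product_bp = best$r$end - best$f$start + 1L,
    fwd_tm = best$f$tm, rev_tm = best$r$tm,
    stringsAsFactors = FALSE)
}

compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' Design primer pairs for every locus of a catalog
#'
#' Applies [design_marker()] to each catalog row; loci without a feasible
#' pair are skipped (and reported in the `failed` attribute).
#'
#' @inheritParams design_marker
#' @param catalog catalog from [scan_genome()].
#' @param verbose print a one-line summary.
#' @return marker table (one row per designed pair) with attribute `failed`
#'   (marker_ids of loci without a pair).
#' @export
design_markers <- function(genome, catalog, constraints = primer_constraints(),
                           verbose = FALSE) {
  seqs <- as_named_sequences(genome)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    design_marker(seqs, catalog[i, ], constraints)
  })
  got <- !vapply(rows, is.null, TRUE)
  out <- if (any(got)) do.call(rbind, rows[got]) else NULL
  if (is.null(out)) {
    out <- data.frame(marker_id = character(), seq_id = character(),
                      ssr_start = integer(), ssr_end = integer(),
                      motif = character(), fwd_seq = character(),
                      rev_seq = character(), fwd_start = integer(),
                      fwd_end = integer(), rev_start = integer(),
                      rev_end = integer(), expected_product_bp = integer(),
                      fwd_tm = numeric(), rev_tm = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "failed") <- if ("marker_id" %in% names(catalog))
    catalog$marker_id[!got] else which(!got)
  if (verbose) {
    message(sprintf("designed %d/%d primer pairs (%.2f%%)",
                    sum(got), nrow(catalog), 100 * sum(got) / max(1L, nrow(catalog))))
  }
  out
}
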