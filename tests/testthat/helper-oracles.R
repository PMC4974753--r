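# Independent brute-force oracles. These deliberately re-derive every result
# from first principles with different code paths than the package.

# --- SSR scanning ----------------------------------------------------------

# enumerate every (start, unit_length) and count complete unit copies by
# direct substring comparison; keep left-maximal, threshold-passing runs
# whose motif is not a repetition of a shorter unit
brute_scan <- function(seq, classes = motif_classes()) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  acgt <- ch %in% c("A", "C", "G", "T")
  prim <- function(m) {
    u <- nchar(m)
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L &&
          paste(rep(substr(m, 1L, d), u / d), collapse = "") == m) return(FALSE)
    }
    TRUE
  }
  res <- list()
  for (k in seq_len(nrow(classes))) {
    u <- classes$unit_length[k]
    minrep <- classes$min_repeats[k]
    for (s in seq_len(max(0L, n - u * minrep + 1L))) {
      unit <- ch[s:(s + u - 1L)]
      if (!all(acgt[s:(s + u - 1L)])) next
      reps <- 1L
      while (s + (reps + 1L) * u - 1L <= n &&
             all(acgt[(s + reps * u):(s + (reps + 1L) * u - 1L)]) &&
             identical(ch[(s + reps * u):(s + (reps + 1L) * u - 1L)], unit)) {
        reps <- reps + 1L
      }
      if (reps < minrep) next
      # left-maximality: the match chain must not start earlier
      if (s > 1L && acgt[s - 1L] && acgt[s - 1L + u] &&
          ch[s - 1L] == ch[s - 1L + u]) next
      if (!prim(paste(unit, collapse = ""))) next
      res[[length(res) + 1L]] <- data.frame(
        start = s, end = s + reps * u - 1L,
        motif = paste(unit, collapse = ""), unit_length = u,
        repeat_count = reps, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit_length), ]
  rownames(out) <- NULL
  out
}

# --- primer binding and amplification --------------------------------------

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# all-offsets scan of one pattern over the plus strand of one sequence,
# counting mismatches inside/outside the 5' window by vectorized comparison
brute_scan_pattern <- function(seq, pattern, window_positions) {
  t <- utf8ToInt(seq)
  p <- utf8ToInt(pattern)
  L <- length(p)
  N <- length(t) - L + 1L
  if (N < 1L) return(data.frame(start = integer(), mismatches = integer()))
  mm_win <- integer(N)
  mm_rest <- integer(N)
  for (j in seq_len(L)) {
    neq <- t[j:(j + N - 1L)] != p[j]
    if (j %in% window_positions) mm_win <- mm_win + neq else mm_rest <- mm_rest + neq
  }
  data.frame(start = seq_len(N), mm_win = mm_win, mm_rest = mm_rest)
}

brute_sites <- function(primer, seqs, rule = match_rule()) {
  primer <- toupper(primer)
  L <- nchar(primer)
  w <- rule$five_prime_window
  cap <- min(rule$max_5prime_mismatches, floor(L * (1 - rule$min_identity) + 1e-9))
  out <- list()
  for (sid in names(seqs)) {
    plus <- brute_scan_pattern(seqs[[sid]], primer, seq_len(w))
    plus <- plus[plus$mm_rest == 0L & plus$mm_win <= cap, , drop = FALSE]
    rc <- oracle_revcomp(primer)
    minus <- brute_scan_pattern(seqs[[sid]], rc, (L - w + 1L):L)
    minus <- minus[minus$mm_rest == 0L & minus$mm_win <= cap, , drop = FALSE]
    if (nrow(plus)) out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, start = plus$start, end = plus$start + L - 1L,
      strand = "+", mismatches = plus$mm_win, stringsAsFactors = FALSE)
    if (nrow(minus)) out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, start = minus$start, end = minus$start + L - 1L,
      strand = "-", mismatches = minus$mm_win, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(match(out$seq_id, names(seqs)), out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

brute_amplify <- function(marker, seqs, rule = match_rule(),
                          bounds = c(50L, 3000L)) {
  fs <- brute_sites(marker$fwd_seq[1L], seqs, rule)
  rs <- brute_sites(marker$rev_seq[1L], seqs, rule)
  res <- list()
  combos <- list(list(a = fs, b = rs), list(a = rs, b = fs))
  for (cb in combos) {
    a <- cb$a[cb$a$strand == "+", , drop = FALSE]
    b <- cb$b[cb$b$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$seq_id[i] != b$seq_id[j]) next
      len <- b$end[j] - a$start[i] + 1L
      if (len < bounds[1L] || len > bounds[2L]) next
      if (b$start[j] <= a$start[i]) next
      res[[length(res) + 1L]] <- data.frame(
        seq_id = a$seq_id[i], start = a$start[i], end = b$end[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, res))
  out <- out[order(match(out$seq_id, names(seqs)), out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# --- misc helpers -----------------------------------------------------------

# canonical key for a set of marker ids, for order-free block comparison
block_key <- function(ids) {
  vapply(ids, function(x) paste(sort(x), collapse = ","), "")
}

expect_same_blocks <- function(blocks, truth) {
  expect_equal(nrow(blocks), nrow(truth))
  kb <- block_key(blocks$marker_ids)
  kt <- block_key(truth$marker_ids)
  expect_setequal(kb, kt)
  expect_equal(blocks$orientation[order(kb)], truth$orientation[order(kt)])
}

# scalar multiset-intersection count between two diploid genotypes
oracle_shared_alleles <- function(a1, a2, b1, b2) {
  s <- 0L
  pool <- c(b1, b2)
  for (x in c(a1, a2)) {
    hit <- match(x, pool)
    if (!is.na(hit)) {
      s <- s + 1L
      pool <- pool[-hit]
    }
  }
  s
}

# nearest-neighbor Tm re-derivation (same published parameter table, typed
# and summed independently via a step-pair lookup on both orientations)
oracle_tm <- function(primer, Na = 0.05, conc = 50e-9) {
  p <- toupper(primer)
  n <- nchar(p)
  tab <- rbind(
    c("AA", -7.9, -22.2), c("AT", -7.2, -20.4), c("TA", -7.2, -21.3),
    c("CA", -8.5, -22.7), c("GT", -8.4, -22.4), c("CT", -7.8, -21.0),
    c("GA", -8.2, -22.2), c("CG", -10.6, -27.2), c("GC", -9.8, -24.4),
    c("GG", -8.0, -19.9))
  steps <- substring(p, 1:(n - 1L), 2:n)
  dh <- 0; ds <- 0
  for (s in steps) {
    row <- which(tab[, 1L] == s)
    if (!length(row)) {
      # look up the step written on the complementary strand
      s2 <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
      row <- which(tab[, 1L] == s2)
    }
    dh <- dh + as.numeric(tab[row, 2L])
    ds <- ds + as.numeric(tab[row, 3L])
  }
  for (b in c(substr(p, 1L, 1L), substr(p, n, n))) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(Na)
  dh * 1000 / (ds + 1.987 * log(conc / 4)) - 273.15
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
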