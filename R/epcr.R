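#' Primer-to-template match rule for electronic PCR
#'
#' The asymmetric mismatch rule used for cross-species marker screening: up
#' to `max_5prime_mismatches` mismatches are tolerated, but only within the
#' `five_prime_window` 5'-most bases of the primer; every position outside
#' that window -- the whole 3' portion, including the 3' terminus -- must
#' match exactly; overall identity must reach `min_identity`; gaps are never
#' allowed. For a 20-mer at the 0.90 identity floor this admits at most 2
#' mismatches even though the window cap is 5; both thresholds are enforced
#' jointly.
#'
#' @param max_5prime_mismatches mismatch cap inside the 5' window.
#' @param five_prime_window window size in nt from the 5' end.
#' @param min_identity minimum overall fractional identity.
#' @return a list of class `match_rule`.
#' @export
match_rule <- function(max_5prime_mismatches = 5L, five_prime_window = 5L,
                       min_identity = 0.90) {
  stopifnot(max_5prime_mismatches >= 0L, five_prime_window >= 0L,
            min_identity >= 0, min_identity <= 1)
  structure(list(max_5prime_mismatches = as.integer(max_5prime_mismatches),
                 five_prime_window = as.integer(five_prime_window),
                 min_identity = as.numeric(min_identity)),
            class = "match_rule")
}

empty_sites <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Find primer binding sites on a target genome
#'
#' Returns every ungapped alignment of the primer, on either strand, that
#' satisfies the [match_rule()]. Coordinates are 1-based inclusive on the
#' plus strand; `strand = "-"` sites are matches of the primer to the minus
#' strand (its reverse complement matches the reported plus-strand span),
#' and there the primer's 5' window corresponds to the right end of the
#' span.
#'
#' @param primer a single unambiguous DNA string, 15--40 nt.
#' @param target genome as accepted by [scan_genome()].
#' @param rule a [match_rule()].
#' @return `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `mismatches`, sorted by position.
#' @export
find_binding_sites <- function(primer, target, rule = match_rule()) {
  primer <- toupper(primer)
  stopifnot(length(primer) == 1L)
  L <- nchar(primer)
  if (L < 15L || L > 40L || grepl("[^ACGT]", primer)) {
    stop("primer must be an unambiguous DNA string of 15-40 nt")
  }
  if (L < rule$five_prime_window + 5L) {
    stop("primer shorter than five_prime_window + 5")
  }
  seqs <- as_named_sequences(target)
  rc <- revcomp(primer)
  out <- lapply(names(seqs), function(sid) {
    plus <- cpp_scan_primer(seqs[[sid]], primer, rule$five_prime_window,
                            rule$max_5prime_mismatches, rule$min_identity, TRUE)
    minus <- cpp_scan_primer(seqs[[sid]], rc, rule$five_prime_window,
                             rule$max_5prime_mismatches, rule$min_identity, FALSE)
    rbind(
      if (nrow(plus)) data.frame(seq_id = sid, start = plus$start,
                                 end = plus$start + L - 1L, strand = "+",
                                 mismatches = plus$mismatches,
                                 stringsAsFactors = FALSE),
      if (nrow(minus)) data.frame(seq_id = sid, start = minus$start,
                                  end = minus$start + L - 1L, strand = "-",
                                  mismatches = minus$mismatches,
                                  stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_sites())
  out <- out[order(match(out$seq_id, names(seqs)), out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

empty_amplicons <- function() {
  data.frame(marker_id = character(), seq_id = character(), start = integer(),
             end = integer(), length = integer(), fwd_mm = integer(),
             rev_mm = integer(), fwd_primer = character(),
             stringsAsFactors = FALSE)
}

#' Predict electronic-PCR products of a marker on a target genome
#'
#' Pairs binding sites of the two primers in convergent orientation (one
#' primer on the plus strand, the other on the minus strand, 3' ends facing
#' each other) and keeps pairs whose outer span lies within
#' `product_bounds`. Both primer-role orientations are considered.
#'
#' @param marker one-row marker `data.frame` from [design_marker()] (needs
#'   `fwd_seq`, `rev_seq`; `marker_id` carried through).
#' @param target genome as accepted by [scan_genome()].
#' @param rule a [match_rule()].
#' @param product_bounds amplicon length bounds in bp (default
#'   `c(50, 3000)`).
#' @return `data.frame` with one row per product: `marker_id`, `seq_id`,
#'   `start`, `end`, `length`, `fwd_mm`, `rev_mm`, `fwd_primer` (`"+"` when
#'   the forward primer is the plus-strand site), deduplicated and sorted.
#' @export
amplify <- function(marker, target, rule = match_rule(),
                    product_bounds = c(50L, 3000L)) {
  stopifnot(length(product_bounds) == 2L,
            product_bounds[1L] <= product_bounds[2L])
  if (product_bounds[1L] < nchar(marker$fwd_seq[1L]) + nchar(marker$rev_seq[1L])) {
    stop("product_bounds minimum is smaller than the summed primer lengths")
  }
  seqs <- as_named_sequences(target)
  fsites <- find_binding_sites(marker$fwd_seq[1L], seqs, rule)
  rsites <- find_binding_sites(marker$rev_seq[1L], seqs, rule)
  mid <- if ("marker_id" %in% names(marker)) marker$marker_id[1L] else NA_character_

  pair_up <- function(a, b, a_is_fwd) {
    # a: plus-strand sites of one primer; b: minus-strand sites of the other
    res <- list()
    for (sid in intersect(unique(a$seq_id), unique(b$seq_id))) {
      ai <- a[a$seq_id == sid, , drop = FALSE]
      bi <- b[b$seq_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(ai))) {
        len <- bi$end - ai$start[i] + 1L
        ok <- which(len >= product_bounds[1L] & len <= product_bounds[2L] &
                      bi$start > ai$start[i])
        if (!length(ok)) next
        res[[length(res) + 1L]] <- data.frame(
          marker_id = mid, seq_id = sid, start = ai$start[i],
          end = bi$end[ok], length = len[ok],
          fwd_mm = if (a_is_fwd) ai$mismatches[i] else bi$mismatches[ok],
          rev_mm = if (a_is_fwd) bi$mismatches[ok] else ai$mismatches[i],
          fwd_primer = if (a_is_fwd) "+" else "-",
          stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }

  amps <- rbind(
    pair_up(fsites[fsites$strand == "+", ], rsites[rsites$strand == "-", ], TRUE),
    pair_up(rsites[rsites$strand == "+", ], fsites[fsites$strand == "-", ], FALSE))
  if (is.null(amps) || nrow(amps) == 0L) return(empty_amplicons())
  amps <- amps[!duplicated(amps[c("seq_id", "start", "end")]), , drop = FALSE]
  amps <- amps[order(match(amps$seq_id, names(seqs)), amps$start, amps$end), ]
  rownames(amps) <- NULL
  amps
}

#' Classify markers by electronic-PCR copy number on a target genome
#'
#' Runs [amplify()] for every marker and splits the set into single-copy
#' markers (exactly one product; the cross-species transferable class),
#' multi-copy markers (two or more products) and markers with no product.
#'
#' @param markers marker table from [design_markers()].
#' @param target genome as accepted by [scan_genome()].
#' @inheritParams amplify
#' @return list of class `transfer_table`: `counts` (`marker_id`,
#'   `n_products`), `single_copy`, `multi_copy`, `no_product` (character
#'   vectors of marker ids), `amplicons` (row-bound product table).
#' @export
classify_transferability <- function(markers, target, rule = match_rule(),
                                     product_bounds = c(50L, 3000L)) {
  stopifnot(nrow(markers) > 0L)
  seqs <- as_named_sequences(target)
  amps <- lapply(seq_len(nrow(markers)), function(i) {
    amplify(markers[i, ], seqs, rule, product_bounds)
  })
  n <- vapply(amps, nrow, 0L)
  counts <- data.frame(marker_id = markers$marker_id, n_products = n,
                       stringsAsFactors = FALSE)
  out <- list(counts = counts,
              single_copy = markers$marker_id[n == 1L],
              multi_copy = markers$marker_id[n >= 2L],
              no_product = markers$marker_id[n == 0L],
              amplicons = do.call(rbind, amps))
  class(out) <- "transfer_table"
  out
}

#' @export
print.transfer_table <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf(
    "transfer_table: %d markers tested; %d single-copy (%.2f%%), %d multi-copy, %d without product\n",
    n, length(x$single_copy), 100 * length(x$single_copy) / n,
    length(x$multi_copy), length(x$no_product)))
  invisible(x)
}

#' Markers single-copy in every target genome
#'
#' Intersects the single-copy sets of two or more [classify_transferability()]
#' results over a common marker universe.
#'
#' @param ... two or more `transfer_table` objects (or one list of them).
#' @return character vector of marker ids single-copy in every table.
#' @export
intersect_transfer_sets <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "transfer_table")) tabs <- tabs[[1L]]
  stopifnot(length(tabs) >= 2L)
  universes <- lapply(tabs, function(t) t$counts$marker_id)
  common <- Reduce(intersect, universes)
  if (length(common) == 0L) stop("transfer tables have disjoint marker universes")
  Reduce(intersect, lapply(tabs, function(t) t$single_copy))
}

#' Annotate amplicons against genomic feature intervals
#'
#' Labels a marker genic when any of its amplicons overlaps at least 1 bp of
#' a feature interval (the interval-overlap surrogate for a
#' sequence-similarity search against transcript databases).
#'
#' @param amplicons amplicon `data.frame` ([amplify()] output rows).
#' @param features `data.frame` with `seq_id`, `start`, `end` and optionally
#'   `type` (1-based inclusive), or a `GRanges` (e.g. from
#'   [read_gff3_intervals()]).
#' @param genome_seq_ids optional character vector of valid sequence names;
#'   features on other sequences are dropped with a warning.
#' @return list: `per_marker` (`marker_id`, `genic`, `feature_types`),
#'   `n_genic`.
#' @export
annotate_markers <- function(amplicons, features, genome_seq_ids = NULL) {
  if (methods::is(features, "GRanges")) {
    features <- data.frame(
      seq_id = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features),
      end = GenomicRanges::end(features),
      type = if ("type" %in% names(S4Vectors::mcols(features)))
        as.character(S4Vectors::mcols(features)$type) else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!"type" %in% names(features)) features$type <- NA_character_
  if (!is.null(genome_seq_ids)) {
    off <- !(features$seq_id %in% genome_seq_ids)
    if (any(off)) {
      warning(sprintf("skipping %d feature(s) on unknown sequence(s): %s",
                      sum(off), paste(unique(features$seq_id[off]), collapse = ", ")))
      features <- features[!off, , drop = FALSE]
    }
  }
  amp_gr <- GenomicRanges::GRanges(amplicons$seq_id,
                                   IRanges::IRanges(amplicons$start, amplicons$end))
  feat_gr <- GenomicRanges::GRanges(features$seq_id,
                                    IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(amp_gr, feat_gr, minoverlap = 1L)
  ids <- unique(amplicons$marker_id)
  genic_markers <- unique(amplicons$marker_id[S4Vectors::queryHits(hits)])
  types <- vapply(ids, function(m) {
    rows <- S4Vectors::subjectHits(hits)[amplicons$marker_id[S4Vectors::queryHits(hits)] == m]
    tt <- unique(features$type[rows])
    tt <- tt[!is.na(tt)]
    if (length(tt)) paste(sort(tt), collapse = ",") else NA_character_
  }, "", USE.NAMES = FALSE)
  per_marker <- data.frame(marker_id = ids, genic = ids %in% genic_markers,
                           feature_types = types, stringsAsFactors = FALSE)
  list(per_marker = per_marker, n_genic = sum(per_marker$genic))
}
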