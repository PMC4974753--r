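ssr_locus_columns <- c("seq_id", "start", "end", "motif", "canonical_motif",
                       "unit_length", "repeat_count", "kind", "member_motifs")

empty_ssr_loci <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             motif = character(), canonical_motif = character(),
             unit_length = integer(), repeat_count = integer(),
             kind = character(), member_motifs = character(),
             stringsAsFactors = FALSE)
}

#' Scan one nucleotide sequence for perfect microsatellites
#'
#' Finds every maximal perfect tandem array whose repeat unit is 2--8 bp and
#' whose number of complete units reaches its class threshold (see
#' [motif_classes()]). Each maximal run is reported exactly once, under its
#' shortest generating unit: a run whose apparent motif is itself a
#' repetition of a shorter unit (e.g. ATAT) is reported only under the
#' shorter unit's class. Overlapping runs of *different* families are all
#' reported. Coordinates are 1-based inclusive and span complete units only.
#' IUPAC ambiguity codes (N etc.) terminate runs: a locus never spans an
#' ambiguous base.
#'
#' @param seq a single DNA string (character scalar or
#'   [Biostrings::DNAString]); case-insensitive.
#' @param seq_id name recorded in the `seq_id` column.
#' @param classes motif-class table as returned by [motif_classes()].
#' @return A `data.frame` of perfect SSR loci with columns `seq_id`, `start`,
#'   `end`, `motif`, `canonical_motif`, `unit_length`, `repeat_count`,
#'   `kind` (`"perfect"`), `member_motifs` (`NA` for perfect loci), sorted by
#'   position.
#' @examples
#' scan_sequence(strrep("AT", 9))      # exactly at the dinucleotide threshold
#' scan_sequence(strrep("AT", 8))      # below threshold: empty
#' @seealso [scan_genome()], [merge_compound()]
#' @export
scan_sequence <- function(seq, seq_id = "seq", classes = motif_classes()) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L, nrow(classes) > 0L)
  n <- nchar(seq)
  if (n == 0L) return(empty_ssr_loci())

  r <- charToRaw(seq)
  bad <- which(!(r %in% charToRaw("ACGTURYSWKMBDHVN")))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' in '%s' at offset %d",
                 rawToChar(r[bad[1L]]), seq_id, bad[1L]))
  }
  unamb <- r %in% charToRaw("ACGT")

  out <- vector("list", 64L)
  n_out <- 0L
  for (k in seq_len(nrow(classes))) {
    u <- classes$unit_length[k]
    minrep <- classes$min_repeats[k]
    if (n < u * minrep) next
    idx <- seq_len(n - u)
    # position i continues a perfect array of unit u when base i equals base i+u
    eq <- (r[idx] == r[idx + u]) & unamb[idx] & unamb[idx + u]
    rl <- rle(eq)
    run_end <- cumsum(rl$lengths)
    run_start <- run_end - rl$lengths + 1L
    hits <- which(rl$values & rl$lengths >= (minrep - 1L) * u)
    for (i in hits) {
      s <- run_start[i]
      reps <- rl$lengths[i] %/% u + 1L   # complete units in the maximal run
      motif <- substr(seq, s, s + u - 1L)
      if (!is_primitive_motif(motif)) next
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- data.frame(
        seq_id = seq_id, start = s, end = s + reps * u - 1L,
        motif = motif, unit_length = u, repeat_count = reps,
        stringsAsFactors = FALSE)
    }
  }
  if (n_out == 0L) return(empty_ssr_loci())
  loci <- do.call(rbind, out[seq_len(n_out)])
  loci$canonical_motif <- canonical_motif(loci$motif)
  loci$kind <- "perfect"
  loci$member_motifs <- NA_character_
  loci <- loci[order(loci$start, loci$unit_length), ssr_locus_columns]
  rownames(loci) <- NULL
  loci
}

#' Scan a genome and build an SSR catalog
#'
#' Runs [scan_sequence()] over every record of a genome and assigns marker
#' identifiers (`prefix` + zero-padded ordinal in genome order, e.g.
#' `ClSSR00001`).
#'
#' @param genome a named character vector, a [Biostrings::DNAStringSet], or a
#'   path to a (multi-record) FASTA file.
#' @param classes motif-class table, see [motif_classes()].
#' @param prefix marker-id prefix (default `"ClSSR"`).
#' @param id_width zero-padding width of the ordinal.
#' @return An SSR catalog: the locus `data.frame` of [scan_sequence()] with a
#'   leading `marker_id` column, plus attribute `genome_length` (total bp
#'   scanned) and `seq_lengths` (named, per record).
#' @seealso [summarize_catalog()], [write_catalog()]
#' @export
scan_genome <- function(genome, classes = motif_classes(),
                        prefix = "ClSSR", id_width = 5L) {
  seqs <- as_named_sequences(genome)
  loci <- do.call(rbind, lapply(names(seqs), function(id) {
    scan_sequence(seqs[[id]], seq_id = id, classes = classes)
  }))
  if (is.null(loci)) loci <- empty_ssr_loci()
  loci <- loci[order(match(loci$seq_id, names(seqs)), loci$start, loci$unit_length), ]
  rownames(loci) <- NULL
  catalog <- cbind(
    data.frame(marker_id = marker_ids(nrow(loci), prefix, id_width),
               stringsAsFactors = FALSE),
    loci)
  attr(catalog, "genome_length") <- sum(nchar(seqs))
  attr(catalog, "seq_lengths") <- vapply(seqs, nchar, 0L)
  catalog
}

marker_ids <- function(n, prefix = "ClSSR", width = 5L) {
  if (n == 0L) return(character())
  sprintf(paste0("%s%0", width, "d"), prefix, seq_len(n))
}

# normalize genome inputs to a named character vector of uppercase sequences
as_named_sequences <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "XStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    stop("genome must be a named character vector, DNAStringSet, or FASTA path")
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    names(genome) <- paste0("seq", seq_along(genome))
  }
  toupper(genome)
}

#' Merge neighbouring SSR loci into compound loci
#'
#' Adjacent loci on the same sequence separated by at most `max_interruption`
#' interrupting bases are merged into one compound locus that records its
#' member motifs in order. Loci further apart pass through unchanged. Merging
#' is transitive (a chain of close neighbours becomes one compound) and
#' order-independent for a fixed input.
#'
#' @param loci SSR locus `data.frame` from [scan_sequence()] or a catalog
#'   from [scan_genome()].
#' @param max_interruption maximum number of interrupting bases (default
#'   100, the conventional compound-SSR interruption limit).
#' @return A locus `data.frame` in which merged rows have `kind =
#'   "compound"`, `member_motifs` a comma-separated list, and `NA`
#'   `unit_length`/`repeat_count`; `marker_id`s are reassigned in genome
#'   order when the input carries them.
#' @export
merge_compound <- function(loci, max_interruption = 100L) {
  if (!is.numeric(max_interruption) || length(max_interruption) != 1L ||
      is.na(max_interruption) || max_interruption < 0) {
    stop("max_interruption must be a single non-negative number")
  }
  had_ids <- "marker_id" %in% names(loci)
  prefix_guess <- if (had_ids && nrow(loci)) sub("[0-9]+$", "", loci$marker_id[1L]) else "ClSSR"
  attrs <- attributes(loci)[c("genome_length", "seq_lengths")]
  loci <- loci[order(loci$seq_id, loci$start, loci$end), , drop = FALSE]

  merged <- list()
  for (sid in unique(loci$seq_id)) {
    sub <- loci[loci$seq_id == sid, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gap_ok <- c(FALSE, sub$start[-1L] - sub$end[-nrow(sub)] - 1L <= max_interruption)
    group <- cumsum(!gap_ok)
    for (g in unique(group)) {
      rows <- sub[group == g, , drop = FALSE]
      if (nrow(rows) == 1L) {
        merged[[length(merged) + 1L]] <- rows[ssr_locus_columns]
      } else {
        members <- rows$motif
        merged[[length(merged) + 1L]] <- data.frame(
          seq_id = sid, start = min(rows$start), end = max(rows$end),
          motif = paste(members, collapse = "+"),
          canonical_motif = NA_character_,
          unit_length = NA_integer_, repeat_count = NA_integer_,
          kind = "compound",
          member_motifs = paste(members, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(merged)) do.call(rbind, merged) else empty_ssr_loci()
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (had_ids) {
    out <- cbind(data.frame(marker_id = marker_ids(nrow(out), prefix_guess),
                            stringsAsFactors = FALSE), out)
  }
  attributes(out)[names(attrs)] <- attrs
  out
}
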