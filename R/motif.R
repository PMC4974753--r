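#' Microsatellite motif classes and detection thresholds
#'
#' Returns the table of repeat-unit classes searched by [scan_sequence()].
#' Only motifs of 2--8 bp are considered (mononucleotide runs are excluded,
#' as they cannot be told apart from sequencing or assembly error). Each class
#' carries a minimum total array length in bp; the minimum number of complete
#' repeat units is the smallest integer `r` with `r * unit_length >=
#' min_total_length`.
#'
#' The default minimum lengths are 18 bp for di- to tetranucleotides, 20 bp
#' for penta-, 24 bp for hexa-, 21 bp for hepta- and 24 bp for
#' octonucleotides, giving minimum repeat numbers 9, 6, 5, 4, 4, 3 and 3.
#' Note the tetranucleotide threshold (18 bp) is not a multiple of 4, so the
#' ceiling rule yields 5 complete units (20 bp).
#'
#' @return A `data.frame` with columns `class_name`, `unit_length`,
#'   `min_total_length`, `min_repeats`.
#' @examples
#' motif_classes()
#' @export
motif_classes <- function() {
  cls <- data.frame(
    class_name = c("di", "tri", "tetra", "penta", "hexa", "hepta", "octo"),
    unit_length = 2:8,
    min_total_length = c(18L, 18L, 18L, 20L, 24L, 21L, 24L),
    stringsAsFactors = FALSE
  )
  cls$min_repeats <- as.integer(ceiling(cls$min_total_length / cls$unit_length))
  cls
}

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; IUPAC ambiguity codes are complemented
#' too (N -> N, R -> Y, ...).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "", USE.NAMES = FALSE)
}

# TRUE when the motif is not a tandem repetition of a shorter unit
# (e.g. "ATAT" is a repetition of "AT" and therefore not a valid
# tetranucleotide motif).
is_primitive_motif <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n %/% 2)) {
    if (n %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, n %/% d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

cyclic_rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i) {
    paste0(substr(x, i, n), substr(x, 1L, i - 1L))
  }, "", USE.NAMES = FALSE)
}

#' Canonical representative of a motif family
#'
#' Motifs that are cyclic rotations of each other, or rotations of each
#' other's reverse complement, describe the same microsatellite family
#' (AG = GA = CT = TC). The canonical motif is the lexicographically smallest
#' string over all cyclic rotations of the motif and of its reverse
#' complement; the operation is idempotent. This is the grouping used to
#' tally motif composition (e.g. the AG/CT family).
#'
#' @param motif character vector of DNA motifs (2--8 bp, unambiguous).
#' @return character vector of canonical motifs.
#' @examples
#' canonical_motif(c("TA", "CT", "GAA"))  # "AT" "AG" "AAG"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  bad <- grepl("[^ACGT]", motif) | nchar(motif) < 2L | nchar(motif) > 8L
  if (any(bad)) {
    stop("invalid motif(s): ", paste(unique(motif[bad]), collapse = ", "))
  }
  uniq <- unique(motif)
  canon <- vapply(uniq, function(m) {
    min(c(cyclic_rotations(m), cyclic_rotations(revcomp(m))))
  }, "", USE.NAMES = FALSE)
  canon[match(motif, uniq)]
}
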