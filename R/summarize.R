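#' Per-class frequency table from class counts
#'
#' Turns raw per-class locus counts into the frequency percentages used in
#' genome-wide SSR surveys (`count / total * 100`).
#'
#' @param counts named numeric vector of per-class locus counts.
#' @return `data.frame` with columns `class_name`, `n`, `frequency_pct`.
#' @examples
#' cf <- class_frequency_table(c(di = 13474, tri = 8947, tetra = 5465,
#'                               penta = 4205, hexa = 2082, hepta = 4059,
#'                               octo = 1291))
#' cf$frequency_pct[cf$class_name == "di"]  # 34.09...
#' @export
class_frequency_table <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) > 0L, all(counts >= 0))
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  data.frame(class_name = names(counts), n = as.numeric(counts),
             frequency_pct = 100 * as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Summarize an SSR catalog
#'
#' Computes the standard genome-survey tallies: per-class counts, frequency
#' percentages and mean repeat numbers; per-chromosome counts and densities
#' (SSRs/Mb); and per-canonical-motif counts within each class. Compound
#' loci are tallied in the totals and per-chromosome table but not in the
#' class or motif tables (they have no single class).
#'
#' @param catalog catalog from [scan_genome()] (or any locus `data.frame`).
#' @param seq_lengths optional named vector of sequence lengths in bp; taken
#'   from the catalog's `seq_lengths` attribute when absent. Densities are
#'   `NA` without lengths.
#' @return A list of class `ssr_summary`: `total` (locus count),
#'   `genome_length`, `density` (SSRs/Mb), `per_class`, `per_chromosome`,
#'   `per_motif` data frames. An empty catalog gives zero-row tables, not an
#'   error.
#' @export
summarize_catalog <- function(catalog, seq_lengths = NULL) {
  if (is.null(seq_lengths)) seq_lengths <- attr(catalog, "seq_lengths")
  genome_length <- if (!is.null(seq_lengths)) sum(seq_lengths) else
    attr(catalog, "genome_length")

  cls <- motif_classes()
  perfect <- catalog[catalog$kind == "perfect", , drop = FALSE]

  if (nrow(catalog) == 0L) {
    out <- list(total = 0L, genome_length = genome_length, density = NA_real_,
                per_class = data.frame(class_name = character(), n = numeric(),
                                       frequency_pct = numeric(),
                                       mean_repeat_number = numeric()),
                per_chromosome = data.frame(seq_id = character(), n = integer(),
                                            length_mb = numeric(),
                                            density_per_mb = numeric()),
                per_motif = data.frame(class_name = character(),
                                       canonical_motif = character(),
                                       n = integer(), pct_within_class = numeric(),
                                       pct_of_total = numeric()))
    class(out) <- "ssr_summary"
    return(out)
  }

  cl_name <- cls$class_name[match(perfect$unit_length, cls$unit_length)]
  counts <- table(factor(cl_name, levels = cls$class_name))
  present <- counts > 0L
  per_class <- class_frequency_table(setNames(as.numeric(counts[present]),
                                              names(counts)[present]))
  per_class$mean_repeat_number <- vapply(per_class$class_name, function(cn) {
    mean(perfect$repeat_count[cl_name == cn])
  }, 0)

  chrom <- unique(catalog$seq_id)
  if (!is.null(seq_lengths)) chrom <- union(names(seq_lengths), chrom)
  n_chr <- vapply(chrom, function(s) sum(catalog$seq_id == s), 0L)
  len_mb <- if (is.null(seq_lengths)) rep(NA_real_, length(chrom)) else
    unname(seq_lengths[chrom]) / 1e6
  per_chromosome <- data.frame(seq_id = chrom, n = n_chr, length_mb = len_mb,
                               density_per_mb = n_chr / len_mb,
                               stringsAsFactors = FALSE, row.names = NULL)

  key <- paste(cl_name, perfect$canonical_motif, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  per_motif <- data.frame(
    class_name = vapply(parts, `[`, "", 1L),
    canonical_motif = vapply(parts, `[`, "", 2L),
    n = as.integer(tab), stringsAsFactors = FALSE)
  class_tot <- setNames(per_class$n, per_class$class_name)
  per_motif$pct_within_class <- 100 * per_motif$n / class_tot[per_motif$class_name]
  per_motif$pct_of_total <- 100 * per_motif$n / nrow(perfect)
  per_motif <- per_motif[order(match(per_motif$class_name, cls$class_name),
                               -per_motif$n), ]
  rownames(per_motif) <- NULL

  out <- list(total = nrow(catalog), genome_length = genome_length,
              density = if (is.null(genome_length)) NA_real_ else
                1e6 * nrow(catalog) / genome_length,
              per_class = per_class, per_chromosome = per_chromosome,
              per_motif = per_motif)
  class(out) <- "ssr_summary"
  out
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR catalog summary: %d loci", x$total))
  if (!is.null(x$genome_length) && !is.na(x$density)) {
    cat(sprintf(" over %.2f Mb (%.1f SSRs/Mb)", x$genome_length / 1e6, x$density))
  }
  cat("\n\nPer class:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat("\nPer chromosome:\n")
  print(x$per_chromosome, row.names = FALSE, digits = 4)
  invisible(x)
}
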