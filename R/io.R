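#' Read a (multi-record) FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]: tolerates wrapped
#' lines, CRLF endings and lowercase; sequences are uppercased and named by
#' the first word of each header.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

# shared TSV conventions: header line, tab-separated, '#' comments
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  # collapse list columns for diff-able output
  for (cn in names(df)) {
    if (is.list(df[[cn]])) {
      df[[cn]] <- vapply(df[[cn]], paste, "", collapse = ",")
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

#' Write / read an SSR catalog as TSV
#'
#' Columns: `marker_id`, `seq_id`, `start`, `end`, `motif`,
#' `canonical_motif`, `unit_length`, `repeat_count`, `kind`,
#' `member_motifs`; 1-based inclusive coordinates.
#'
#' @param catalog catalog from [scan_genome()].
#' @param path TSV file.
#' @return `write_catalog`: `path` invisibly; `read_catalog`: the catalog
#'   `data.frame`.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path, "SSR catalog; 1-based inclusive coordinates")
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv(path)
  int_cols <- intersect(c("start", "end", "unit_length", "repeat_count"), names(df))
  for (cn in int_cols) df[[cn]] <- as.integer(df[[cn]])
  for (cn in intersect(c("marker_id", "seq_id", "motif", "canonical_motif",
                         "kind", "member_motifs"), names(df))) {
    df[[cn]] <- as.character(df[[cn]])
  }
  df
}

#' Write loci as a GFF3 track
#'
#' One `microsatellite` feature per locus, 1-based inclusive per the GFF3
#' convention, with `ID` and `motif` attributes.
#'
#' @param catalog catalog / locus `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(catalog)) {
    ids <- if ("marker_id" %in% names(catalog)) catalog$marker_id
    else paste0("ssr", seq_len(nrow(catalog)))
    writeLines(sprintf(
      "%s\tssrmine\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=%s;motif=%s",
      catalog$seq_id, catalog$start, catalog$end, ids, catalog$motif), con)
  }
  invisible(path)
}

#' Write loci as a BED track
#'
#' BED uses 0-based half-open coordinates; a locus at 1-based `[start, end]`
#' becomes `start-1, end`.
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(catalog, path) {
  ids <- if ("marker_id" %in% names(catalog)) catalog$marker_id
  else paste0("ssr", seq_len(nrow(catalog)))
  lines <- if (nrow(catalog)) {
    sprintf("%s\t%d\t%d\t%s", catalog$seq_id, catalog$start - 1L,
            catalog$end, ids)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read intervals of one feature type from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (e.g. `"CDS"`, `"gene"`); `NULL`
#'   keeps everything.
#' @return `data.frame` with `seq_id`, `start`, `end`, `type` (1-based
#'   inclusive).
#' @export
read_gff3_intervals <- function(path, feature_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8L)) {
    stop(sprintf("malformed GFF3 record in %s at line %d: expected >= 8 fields",
                 path, which(nf < 8L)[1L]))
  }
  df <- data.frame(seq_id = vapply(parts, `[`, "", 1L),
                   type = vapply(parts, `[`, "", 3L),
                   start = as.integer(vapply(parts, `[`, "", 4L)),
                   end = as.integer(vapply(parts, `[`, "", 5L)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("malformed GFF3 coordinates in ", path)
  }
  if (!is.null(feature_type)) df <- df[df$type %in% feature_type, , drop = FALSE]
  rownames(df) <- NULL
  df[c("seq_id", "start", "end", "type")]
}

#' Write / read a marker (primer-pair) table as TSV
#'
#' @param markers marker table from [design_markers()].
#' @param path TSV file.
#' @export
write_markers <- function(markers, path) {
  write_tsv(markers, path, "SSR marker primer pairs")
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- read_tsv(path)
  for (cn in intersect(c("ssr_start", "ssr_end", "fwd_start", "fwd_end",
                         "rev_start", "rev_end", "expected_product_bp"),
                       names(df))) {
    df[[cn]] <- as.integer(df[[cn]])
  }
  df
}

#' Write / read an amplicon table as TSV
#'
#' @param amplicons amplicon `data.frame` from [amplify()].
#' @param path TSV file.
#' @export
write_amplicons <- function(amplicons, path) {
  write_tsv(amplicons, path, "in silico PCR products; 1-based inclusive")
}

#' @rdname write_amplicons
#' @export
read_amplicons <- function(path) {
  df <- read_tsv(path)
  for (cn in intersect(c("start", "end", "length", "fwd_mm", "rev_mm"), names(df))) {
    df[[cn]] <- as.integer(df[[cn]])
  }
  df
}

#' Write / read shared-marker and block tables as TSV
#'
#' @param x table to write.
#' @param path TSV file.
#' @export
write_shared_markers <- function(x, path) write_tsv(x, path, "shared markers")

#' @rdname write_shared_markers
#' @export
read_shared_markers <- function(path) {
  df <- read_tsv(path)
  for (cn in intersect(c("src_pos", "tgt_pos"), names(df))) df[[cn]] <- as.integer(df[[cn]])
  df
}

#' @rdname write_shared_markers
#' @export
write_blocks <- function(x, path) write_tsv(x, path, "syntenic blocks")

#' Write / read a codominant genotype table
#'
#' STRUCTURE-compatible layout: one row per accession, two columns per
#' marker (`<locus>.1`, `<locus>.2`); `-9` or empty cells mean missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path TSV file.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$accessions)
  out <- data.frame(accession = gm$accessions, stringsAsFactors = FALSE)
  for (j in seq_along(gm$loci)) {
    a1 <- gm$allele1[, j]; a2 <- gm$allele2[, j]
    a1[is.na(a1)] <- "-9"; a2[is.na(a2)] <- "-9"
    out[[paste0(gm$loci[j], ".1")]] <- a1
    out[[paste0(gm$loci[j], ".2")]] <- a2
  }
  write_tsv(out, path, "codominant genotypes; -9 = missing")
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  acc <- as.character(df[[1L]])
  cols <- names(df)[-1L]
  loci <- unique(sub("\\.[12]$", "", cols))
  a1 <- matrix(NA_character_, length(acc), length(loci),
               dimnames = list(acc, loci))
  a2 <- a1
  for (l in loci) {
    c1 <- df[[paste0(l, ".1")]]; c2 <- df[[paste0(l, ".2")]]
    if (is.null(c1) || is.null(c2)) {
      stop("genotype table lacks paired columns for locus ", l)
    }
    c1 <- as.character(c1); c2 <- as.character(c2)
    c1[c1 %in% c("-9", "")] <- NA_character_
    c2[c2 %in% c("-9", "")] <- NA_character_
    a1[, l] <- c1; a2[, l] <- c2
  }
  genotype_matrix(a1, a2, accessions = acc, loci = loci)
}

#' Read a replicate log-probability table
#'
#' Expects columns `K`, `run`, `LnPD` (tab-separated, `#` comments).
#'
#' @param path TSV file.
#' @return `data.frame` suitable for [evanno_delta_k()].
#' @export
read_structure_runs <- function(path) {
  df <- read_tsv(path)
  need <- c("K", "run", "LnPD")
  if (!all(need %in% names(df))) {
    stop("structure-run table must have columns K, run, LnPD")
  }
  df$K <- as.integer(df$K)
  df
}

#' Write a tree in Newick format
#'
#' @param tree an [ape] `phylo` object (e.g. from [upgma()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a planting record as JSON
#'
#' Serializes generator ground truth (lists and data frames) so oracle
#' tests can reload it verbatim.
#'
#' @param record list or `data.frame` from a generator.
#' @param path JSON file.
#' @export
write_planting_record <- function(record, path) {
  jsonlite::write_json(record, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_planting_record
#' @export
read_planting_record <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
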