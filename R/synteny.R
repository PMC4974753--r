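#' Build a shared-marker table from two transferability screens
#'
#' Combines a source-genome marker table with the amplicons of a target
#' screen, keeping single-copy markers only, with positions taken as
#' midpoints (source: SSR array midpoint; target: amplicon midpoint).
#'
#' @param markers marker table from [design_markers()] (source positions).
#' @param transfer `transfer_table` from [classify_transferability()] on the
#'   target genome.
#' @param drop_seq_ids source sequences to exclude (e.g. the unanchored
#'   pseudo-chromosome `"chr0"`); such markers count for transferability
#'   but are dropped from synteny.
#' @return `data.frame` with `marker_id`, `src_chr`, `src_pos`, `tgt_chr`,
#'   `tgt_pos`.
#' @export
shared_markers <- function(markers, transfer, drop_seq_ids = "chr0") {
  keep <- markers$marker_id %in% transfer$single_copy &
    !(markers$seq_id %in% drop_seq_ids)
  src <- markers[keep, , drop = FALSE]
  amp <- transfer$amplicons
  amp <- amp[match(src$marker_id, amp$marker_id), , drop = FALSE]
  data.frame(marker_id = src$marker_id,
             src_chr = src$seq_id,
             src_pos = as.integer((src$ssr_start + src$ssr_end) %/% 2),
             tgt_chr = amp$seq_id,
             tgt_pos = as.integer((amp$start + amp$end) %/% 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call syntenic blocks from shared markers
#'
#' Walks each source chromosome in source order after assigning every
#' marker its positional rank within its target chromosome. Consecutive
#' markers stay in one block while they share the target chromosome and
#' their target ranks advance by exactly one in a fixed direction
#' (`max_rank_gap` interleaved markers may be skipped, default 0). Runs with
#' at least `min_block_markers` members are emitted as blocks -- collinear
#' when target ranks increase, inverted when they decrease; shorter runs are
#' dropped. Block spans run from first to last member marker on both
#' genomes.
#'
#' @param shared shared-marker `data.frame` (`marker_id`, `src_chr`,
#'   `src_pos`, `tgt_chr`, `tgt_pos`); one row per marker.
#' @param min_block_markers minimum members per block (default 3).
#' @param max_rank_gap interleaved markers that may be skipped between
#'   consecutive members (default 0, the strict rule).
#' @param prefix block-id prefix (default `"SB"`).
#' @return `data.frame` with `block_id`, `src_chr`, `src_start`, `src_end`,
#'   `tgt_chr`, `tgt_start`, `tgt_end`, `n_markers`, `orientation` and list
#'   columns `marker_ids`, `marker_src_pos`.
#' @export
call_blocks <- function(shared, min_block_markers = 3L, max_rank_gap = 0L,
                        prefix = "SB") {
  stopifnot(nrow(shared) > 0L, min_block_markers >= 1L, max_rank_gap >= 0L)
  if (anyDuplicated(shared$marker_id)) {
    stop("duplicate marker_id in shared-marker table: ",
         shared$marker_id[duplicated(shared$marker_id)][1L])
  }
  shared$tgt_rank <- stats::ave(shared$tgt_pos, shared$tgt_chr,
                                FUN = function(p) rank(p, ties.method = "first"))

  blocks <- list()
  for (chr in unique(shared$src_chr)) {
    sub <- shared[shared$src_chr == chr, , drop = FALSE]
    sub <- sub[order(sub$src_pos), , drop = FALSE]
    run_start <- 1L
    dir <- 0L
    flush <- function(from, to, dir) {
      if (to - from + 1L < min_block_markers) return()
      m <- sub[from:to, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <<- data.frame(
        src_chr = chr, src_start = m$src_pos[1L], src_end = m$src_pos[nrow(m)],
        tgt_chr = m$tgt_chr[1L], tgt_start = min(m$tgt_pos),
        tgt_end = max(m$tgt_pos), n_markers = nrow(m),
        orientation = if (dir >= 0L) "collinear" else "inverted",
        marker_ids = I(list(m$marker_id)),
        marker_src_pos = I(list(m$src_pos)),
        stringsAsFactors = FALSE)
    }
    if (nrow(sub) >= 2L) {
      for (j in 2:nrow(sub)) {
        d <- sub$tgt_rank[j] - sub$tgt_rank[j - 1L]
        same_chr <- sub$tgt_chr[j] == sub$tgt_chr[j - 1L]
        step_ok <- same_chr && abs(d) - 1L <= max_rank_gap &&
          (dir == 0L || sign(d) == dir)
        if (step_ok) {
          if (dir == 0L) dir <- sign(d)
        } else {
          flush(run_start, j - 1L, dir)
          run_start <- j
          dir <- 0L
        }
      }
    }
    flush(run_start, nrow(sub), dir)
  }
  if (!length(blocks)) {
    out <- data.frame(block_id = character(), src_chr = character(),
                      src_start = integer(), src_end = integer(),
                      tgt_chr = character(), tgt_start = integer(),
                      tgt_end = integer(), n_markers = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
    out$marker_ids <- I(list())
    out$marker_src_pos <- I(list())
    return(out)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$src_chr, out$src_start), , drop = FALSE]
  out <- cbind(data.frame(block_id = paste0(prefix, seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Chromosome-to-chromosome correspondence table
#'
#' For each source chromosome, tallies the shared markers that its blocks
#' place on each target chromosome; pairs with fewer than `min_markers`
#' shared markers are omitted.
#'
#' @param blocks block table from [call_blocks()].
#' @param min_markers minimum shared markers per listed pair (default 3).
#' @return `data.frame` with `src_chr`, `tgt_chr`, `n_shared`, sorted by
#'   source chromosome and descending count.
#' @export
chromosome_correspondence <- function(blocks, min_markers = 3L) {
  if (nrow(blocks) == 0L) {
    return(data.frame(src_chr = character(), tgt_chr = character(),
                      n_shared = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(n_markers ~ src_chr + tgt_chr, data = blocks, FUN = sum)
  names(agg)[3L] <- "n_shared"
  agg <- agg[agg$n_shared >= min_markers, , drop = FALSE]
  agg <- agg[order(agg$src_chr, -agg$n_shared, agg$tgt_chr), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Blocks conserved across three genomes
#'
#' Intersects two block sets that share the source genome: for every pair of
#' blocks on the same source chromosome, the markers present in both become
#' a candidate conserved block, kept when it has at least `min_members`
#' members. Spans are reported on the source genome over the shared members.
#'
#' @param blocks_a,blocks_b block tables from [call_blocks()] against two
#'   different target genomes, same source genome.
#' @param min_members minimum shared members (default 3).
#' @param prefix conserved-block id prefix.
#' @return `data.frame` with `conserved_id`, `src_chr`, `src_start`,
#'   `src_end`, `n_markers`, `block_a`, `block_b` and list column
#'   `marker_ids`.
#' @export
intersect_blocks <- function(blocks_a, blocks_b, min_members = 3L,
                             prefix = "CB") {
  res <- list()
  for (i in seq_len(nrow(blocks_a))) {
    ja <- which(blocks_b$src_chr == blocks_a$src_chr[i])
    for (j in ja) {
      common <- intersect(blocks_a$marker_ids[[i]], blocks_b$marker_ids[[j]])
      if (length(common) < min_members) next
      pos <- blocks_a$marker_src_pos[[i]][match(common, blocks_a$marker_ids[[i]])]
      res[[length(res) + 1L]] <- data.frame(
        src_chr = blocks_a$src_chr[i], src_start = min(pos), src_end = max(pos),
        n_markers = length(common),
        block_a = blocks_a$block_id[i], block_b = blocks_b$block_id[j],
        marker_ids = I(list(common[order(pos)])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    out <- data.frame(conserved_id = character(), src_chr = character(),
                      src_start = integer(), src_end = integer(),
                      n_markers = integer(), block_a = character(),
                      block_b = character(), stringsAsFactors = FALSE)
    out$marker_ids <- I(list())
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$src_chr, out$src_start), , drop = FALSE]
  out <- cbind(data.frame(conserved_id = paste0(prefix, seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Export Circos-style link records
#'
#' Writes plain-text link records (`src_chr src_start src_end tgt_chr
#' tgt_start tgt_end`) -- one ribbon per block, or one link per marker.
#'
#' @param x block table from [call_blocks()] (`mode = "block"`) or
#'   shared-marker table (`mode = "marker"`).
#' @param path output file.
#' @param mode `"block"` or `"marker"`.
#' @return `path`, invisibly.
#' @export
export_links <- function(x, path, mode = c("block", "marker")) {
  mode <- match.arg(mode)
  lines <- "# circos link records: chr start end chr start end"
  if (nrow(x) > 0L) {
    recs <- if (mode == "block") {
      sprintf("%s %d %d %s %d %d", x$src_chr, x$src_start, x$src_end,
              x$tgt_chr, x$tgt_start, x$tgt_end)
    } else {
      sprintf("%s %d %d %s %d %d", x$src_chr, x$src_pos, x$src_pos,
              x$tgt_chr, x$tgt_pos, x$tgt_pos)
    }
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}
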