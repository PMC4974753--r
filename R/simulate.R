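BASES <- c("A", "C", "G", "T")

# Lightweight tandem-run detector used only inside the generators to
# suppress and verify incidental repeats. Flags every maximal match chain
# reaching its class threshold (no primitivity filtering, no trimming), so
# suppression is at least as strict as the scanner.
detect_tandem_intervals <- function(chars, classes = motif_classes()) {
  n <- length(chars)
  out <- list()
  for (k in seq_len(nrow(classes))) {
    u <- classes$unit_length[k]
    minrep <- classes$min_repeats[k]
    if (n < u * minrep) next
    hit <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    idx <- which(hit)
    if (!length(idx)) next
    grp <- cumsum(c(TRUE, diff(idx) != 1L))
    for (g in split(idx, grp)) {
      m <- length(g)
      if (m >= (minrep - 1L) * u) {
        out[[length(out) + 1L]] <- c(g[1L], g[1L] + m + u - 1L, u)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), unit = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "unit")
  df
}

random_primitive_motif <- function(unit_length) {
  repeat {
    m <- paste(sample(BASES, unit_length, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

#' Generate a genome with planted SSR loci
#'
#' Builds a random A/C/G/T background in which tandem runs reaching any
#' class threshold are rejection-sampled away, then plants `n_loci` perfect
#' microsatellites of known motif, repeat number and position. Junction
#' bases are constrained so a planted array can neither extend nor shift,
#' and the final genome is verified so that the planted loci are exactly the
#' threshold-passing repeats it contains. Real genomes do not have this
#' clean-background property; it is what makes exact recall/precision
#' testing possible.
#'
#' @param length total genome length in bp (split evenly over chromosomes).
#' @param n_loci number of planted loci.
#' @param class_mix named weights over the seven classes (default uniform).
#' @param n_chromosomes number of chromosomes (named `chr1`, `chr2`, ...).
#' @param min_gap minimum bp between planted loci and from chromosome ends.
#' @param extra_repeats loci get `min_repeats + sample(0:extra_repeats)`
#'   units.
#' @param seed integer seed (sets the RNG).
#' @param classes motif-class table.
#' @return list of class `ssr_genome_sim`: `genome` (named character
#'   vector), `record` (planting record: `seq_id`, `start`, `end`, `motif`,
#'   `unit_length`, `repeat_count`, `class_name`), `params`.
#' @export
make_ssr_genome <- function(length = 1e5, n_loci = 50L,
                            class_mix = NULL, n_chromosomes = 1L,
                            min_gap = 30L, extra_repeats = 5L, seed = NULL,
                            classes = motif_classes()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(class_mix)) {
    class_mix <- setNames(rep(1, nrow(classes)), classes$class_name)
  }
  class_mix <- class_mix[classes$class_name]
  class_mix[is.na(class_mix)] <- 0
  names(class_mix) <- classes$class_name

  chr_len <- rep(as.integer(length %/% n_chromosomes), n_chromosomes)
  chr_names <- paste0("chr", seq_len(n_chromosomes))
  chr_of <- if (n_loci > 0L) sort(rep_len(seq_len(n_chromosomes), n_loci)) else integer()

  rec <- list()
  genome <- character(n_chromosomes)
  for (c_i in seq_len(n_chromosomes)) {
    L <- chr_len[c_i]
    k <- sum(chr_of == c_i)
    # choose loci
    loci <- if (k > 0L) {
      cls_i <- sample(seq_len(nrow(classes)), k, replace = TRUE, prob = class_mix)
      data.frame(
        unit_length = classes$unit_length[cls_i],
        class_name = classes$class_name[cls_i],
        repeat_count = classes$min_repeats[cls_i] +
          sample(0:extra_repeats, k, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      data.frame(unit_length = integer(), class_name = character(),
                 repeat_count = integer())
    }
    loci$len <- loci$unit_length * loci$repeat_count
    loci$motif <- vapply(loci$unit_length, random_primitive_motif, "")
    slack <- L - sum(loci$len) - (k + 1L) * min_gap
    if (slack < 0L) stop("infeasible packing: planted loci do not fit")
    w <- runif(k + 1L)
    gaps <- as.integer(min_gap + floor(slack * w / sum(w)))
    starts <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + loci$len[i]
    }
    loci$start <- starts
    loci$end <- starts + loci$len - 1L

    chars <- sample(BASES, L, replace = TRUE)
    # plant
    for (i in seq_len(k)) {
      unit <- strsplit(loci$motif[i], "")[[1L]]
      chars[loci$start[i]:loci$end[i]] <- rep(unit, loci$repeat_count[i])
    }
    chars <- clean_background(chars, loci, classes)
    genome[c_i] <- paste(chars, collapse = "")
    if (k > 0L) {
      loci$seq_id <- chr_names[c_i]
      rec[[length(rec) + 1L]] <-
        loci[c("seq_id", "start", "end", "motif", "unit_length",
               "repeat_count", "class_name")]
    }
  }
  names(genome) <- chr_names
  record <- if (length(rec)) do.call(rbind, rec) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), unit_length = integer(),
               repeat_count = integer(), class_name = character(),
               stringsAsFactors = FALSE)
  rownames(record) <- NULL
  structure(list(genome = genome, record = record,
                 params = list(length = length, n_loci = n_loci,
                               n_chromosomes = n_chromosomes,
                               min_gap = min_gap, seed = seed)),
            class = "ssr_genome_sim")
}

# redraw background until the planted loci are exactly the threshold-passing
# tandem repeats in the chromosome
clean_background <- function(chars, loci, classes, max_iter = 200L) {
  n <- length(chars)
  in_planted <- rep(FALSE, n)
  for (i in seq_len(nrow(loci))) in_planted[loci$start[i]:loci$end[i]] <- TRUE

  enforce_junctions <- function(chars) {
    for (i in seq_len(nrow(loci))) {
      u <- loci$unit_length[i]
      unit <- strsplit(loci$motif[i], "")[[1L]]
      s <- loci$start[i]; e <- loci$end[i]
      if (s > 1L && chars[s - 1L] == unit[u]) {
        chars[s - 1L] <- sample(setdiff(BASES, unit[u]), 1L)
      }
      if (e < n && chars[e + 1L] == unit[1L]) {
        chars[e + 1L] <- sample(setdiff(BASES, unit[1L]), 1L)
      }
    }
    chars
  }

  chars <- enforce_junctions(chars)
  for (iter in seq_len(max_iter)) {
    det <- detect_tandem_intervals(chars, classes)
    contained <- rep(FALSE, nrow(det))
    planted_ok <- rep(FALSE, nrow(loci))
    for (i in seq_len(nrow(loci))) {
      hit <- det$start >= loci$start[i] & det$end <= loci$end[i]
      contained <- contained | hit
      planted_ok[i] <- any(det$unit == loci$unit_length[i] &
                             det$start == loci$start[i] &
                             det$end == loci$end[i])
    }
    extras <- det[!contained, , drop = FALSE]
    if (nrow(extras) == 0L && all(planted_ok)) return(chars)
    for (r in seq_len(nrow(extras))) {
      span <- extras$start[r]:extras$end[r]
      span <- span[!in_planted[span]]
      chars[span] <- sample(BASES, length(span), replace = TRUE)
    }
    chars <- enforce_junctions(chars)
  }
  stop("could not build a clean background around the planted loci")
}

#' Derive a rearranged, diverged partner genome
#'
#' Applies segmental inversions (in place) and translocations (segment
#' appended to another chromosome) to a planted-SSR genome, then point
#' mutations, and records where every planted locus went and which
#' rearranged segment (if any) it belongs to. Segment boundaries are placed
#' midway between marker protection zones, so no planted locus or its
#' primer-bearing flank is ever cut. Unless `stress = TRUE`, mutations
#' avoid a `protect_flank` window around every planted locus (a superset of
#' any primer footprint for amplicons up to 300 bp), so designed markers
#' survive the divergence; with `stress = TRUE` mutations fall anywhere,
#' which is how transfer loss versus mutation rate is studied.
#'
#' @param sim an `ssr_genome_sim` from [make_ssr_genome()], or a list with
#'   `genome` and `record`.
#' @param n_inversions,n_translocations number of segmental operations.
#' @param segment_markers vector of allowed markers-per-segment counts.
#' @param context_markers untouched markers required flanking each segment
#'   and at chromosome ends.
#' @param mutation_rate per-base substitution probability.
#' @param protect_flank protected bp on each side of a planted locus.
#' @param stress if `TRUE`, mutations ignore protection.
#' @param seed integer seed.
#' @return list of class `partner_genome_sim`: `genome`, `markers`
#'   (planting record with `new_chr`, `new_start`, `new_end`, `label`,
#'   `inverted`), `ops` (one row per rearrangement), `params`.
#' @export
derive_partner_genome <- function(sim, n_inversions = 3L, n_translocations = 2L,
                                  segment_markers = 5:8, context_markers = 3L,
                                  mutation_rate = 0, protect_flank = 350L,
                                  stress = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- as_named_sequences(sim$genome)
  rec <- sim$record
  rec <- rec[order(match(rec$seq_id, names(genome)), rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  chr_len <- vapply(genome, nchar, 0L)
  n_ops <- n_inversions + n_translocations

  # marker protection zones; segment boundaries go midway between zones
  zone_lo <- pmax(1L, rec$start - protect_flank)
  zone_hi <- pmin(chr_len[rec$seq_id], rec$end + protect_flank)

  # pick disjoint marker-index windows per chromosome
  free <- lapply(names(genome), function(ch) {
    idx <- which(rec$seq_id == ch)
    if (length(idx) >= 2L * context_markers + min(segment_markers)) {
      list(c(min(idx) + context_markers, max(idx) - context_markers))
    } else list()
  })
  names(free) <- names(genome)

  ops <- list()
  for (op_i in seq_len(n_ops)) {
    sizes <- sample(rep(segment_markers, 2L))  # preference order over allowed sizes
    cand <- list(); sz <- NA_integer_
    for (s_try in unique(sizes)) {
      for (ch in names(free)) {
        for (iv in free[[ch]]) {
          if (iv[2L] - iv[1L] + 1L >= s_try) {
            cand[[length(cand) + 1L]] <- list(chr = ch, lo = iv[1L], hi = iv[2L])
          }
        }
      }
      if (length(cand)) { sz <- s_try; break }
    }
    if (!length(cand)) stop("not enough free markers to place all rearrangements")
    pick <- cand[[sample(length(cand), 1L)]]
    i0 <- sample(pick$lo:(pick$hi - sz + 1L), 1L)
    i1 <- i0 + sz - 1L
    # shrink the free interval, keeping context between segments
    free[[pick$chr]] <- c(
      Filter(function(iv) !(iv[1L] == pick$lo && iv[2L] == pick$hi), free[[pick$chr]]),
      if (i0 - pick$lo >= context_markers + 1L)
        list(c(pick$lo, i0 - context_markers - 1L)),
      if (pick$hi - i1 >= context_markers + 1L)
        list(c(i1 + context_markers + 1L, pick$hi)))
    kind <- if (op_i <= n_inversions) "inversion" else "translocation"
    dest <- if (kind == "translocation") {
      sample(setdiff(names(genome), pick$chr), 1L)
    } else NA_character_
    # bp boundaries midway between neighbouring protection zones
    bp_lo <- (zone_hi[i0 - 1L] + zone_lo[i0]) %/% 2L
    bp_hi <- (zone_hi[i1] + zone_lo[i1 + 1L]) %/% 2L
    if (zone_hi[i0 - 1L] >= zone_lo[i0] || zone_hi[i1] >= zone_lo[i1 + 1L]) {
      stop("marker protection zones overlap; plant loci further apart")
    }
    ops[[op_i]] <- data.frame(
      op = kind, label = paste0(substr(kind, 1L, 3L), op_i),
      src_chr = pick$chr, bp_start = bp_lo, bp_end = bp_hi,
      marker_from = i0, marker_to = i1, dest_chr = dest,
      stringsAsFactors = FALSE)
  }
  ops <- if (length(ops)) do.call(rbind, ops) else
    data.frame(op = character(), label = character(), src_chr = character(),
               bp_start = integer(), bp_end = integer(),
               marker_from = integer(), marker_to = integer(),
               dest_chr = character(), stringsAsFactors = FALSE)

  # layout: each output chromosome is an ordered list of source pieces
  layout <- lapply(names(genome), function(ch) {
    ivs <- ops[ops$src_chr == ch, , drop = FALSE]
    ivs <- ivs[order(ivs$bp_start), , drop = FALSE]
    pieces <- list()
    pos <- 1L
    for (r in seq_len(nrow(ivs))) {
      if (ivs$bp_start[r] > pos) {
        pieces[[length(pieces) + 1L]] <- list(src = ch, s = pos,
                                              e = ivs$bp_start[r] - 1L,
                                              strand = "+", keep = TRUE)
      }
      pieces[[length(pieces) + 1L]] <- list(
        src = ch, s = ivs$bp_start[r], e = ivs$bp_end[r],
        strand = if (ivs$op[r] == "inversion") "-" else "+",
        keep = ivs$op[r] == "inversion", dest = ivs$dest_chr[r])
      pos <- ivs$bp_end[r] + 1L
    }
    if (pos <= chr_len[ch]) {
      pieces[[length(pieces) + 1L]] <- list(src = ch, s = pos, e = chr_len[ch],
                                            strand = "+", keep = TRUE)
    }
    pieces
  })
  names(layout) <- names(genome)
  # move translocated pieces to the end of their destination chromosome
  for (ch in names(layout)) {
    moved <- Filter(function(p) !p$keep, layout[[ch]])
    layout[[ch]] <- Filter(function(p) p$keep, layout[[ch]])
    for (p in moved) {
      p$keep <- TRUE
      layout[[p$dest]] <- c(layout[[p$dest]], list(p))
    }
  }

  # build sequences and the source -> partner coordinate map
  new_genome <- character(length(genome))
  names(new_genome) <- names(genome)
  piece_table <- list()
  for (ch in names(layout)) {
    off <- 0L
    segs <- character()
    for (p in layout[[ch]]) {
      seg <- substr(genome[[p$src]], p$s, p$e)
      if (p$strand == "-") seg <- revcomp(seg)
      segs <- c(segs, seg)
      piece_table[[length(piece_table) + 1L]] <- data.frame(
        src = p$src, s = p$s, e = p$e, strand = p$strand,
        new_chr = ch, off = off, stringsAsFactors = FALSE)
      off <- off + (p$e - p$s + 1L)
    }
    new_genome[ch] <- paste(segs, collapse = "")
  }
  piece_table <- do.call(rbind, piece_table)

  map_pos <- function(chr, pos) {
    r <- which(piece_table$src == chr & piece_table$s <= pos & piece_table$e >= pos)[1L]
    p <- piece_table[r, ]
    new_pos <- if (p$strand == "+") p$off + (pos - p$s + 1L) else
      p$off + (p$e - pos + 1L)
    list(chr = p$new_chr, pos = as.integer(new_pos))
  }

  # marker bookkeeping
  markers <- rec
  markers$label <- "ctx"
  markers$inverted <- FALSE
  for (r in seq_len(nrow(ops))) {
    idx <- ops$marker_from[r]:ops$marker_to[r]
    markers$label[idx] <- ops$label[r]
    if (ops$op[r] == "inversion") markers$inverted[idx] <- TRUE
  }
  mapped_s <- lapply(seq_len(nrow(markers)),
                     function(i) map_pos(markers$seq_id[i], markers$start[i]))
  mapped_e <- lapply(seq_len(nrow(markers)),
                     function(i) map_pos(markers$seq_id[i], markers$end[i]))
  markers$new_chr <- vapply(mapped_s, `[[`, "", "chr")
  s1 <- vapply(mapped_s, `[[`, 0L, "pos")
  s2 <- vapply(mapped_e, `[[`, 0L, "pos")
  markers$new_start <- pmin(s1, s2)
  markers$new_end <- pmax(s1, s2)

  # point mutations
  if (mutation_rate > 0) {
    protected <- lapply(names(new_genome), function(ch) NULL)
    names(protected) <- names(new_genome)
    if (!stress) {
      for (i in seq_len(nrow(markers))) {
        m1 <- map_pos(markers$seq_id[i], max(1L, markers$start[i] - protect_flank))
        m2 <- map_pos(markers$seq_id[i], min(chr_len[markers$seq_id[i]],
                                             markers$end[i] + protect_flank))
        lo <- min(m1$pos, m2$pos); hi <- max(m1$pos, m2$pos)
        protected[[m1$chr]] <- rbind(protected[[m1$chr]], c(lo, hi))
      }
    }
    for (ch in names(new_genome)) {
      L <- nchar(new_genome[ch])
      n_mut <- rbinom(1L, L, mutation_rate)
      if (n_mut == 0L) next
      pos <- sample.int(L, n_mut)
      pr <- protected[[ch]]
      if (!is.null(pr)) {
        keep <- !vapply(pos, function(p) any(p >= pr[, 1L] & p <= pr[, 2L]), TRUE)
        pos <- pos[keep]
      }
      if (!length(pos)) next
      chars <- strsplit(new_genome[ch], "")[[1L]]
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(BASES, b), 1L), "",
                           USE.NAMES = FALSE)
      new_genome[ch] <- paste(chars, collapse = "")
    }
  }

  structure(list(genome = new_genome, markers = markers, ops = ops,
                 params = list(n_inversions = n_inversions,
                               n_translocations = n_translocations,
                               mutation_rate = mutation_rate,
                               protect_flank = protect_flank,
                               stress = stress, seed = seed)),
            class = "partner_genome_sim")
}

#' Expected syntenic-block partition of a planted rearrangement
#'
#' Reads the ground truth straight from the rearrangement bookkeeping: in
#' source order, maximal runs of markers carrying the same segment label
#' (untouched context, a given inversion, or a given translocation) are the
#' expected blocks; a run is inverted exactly when its segment was
#' inverted. Runs below `min_block_markers` are dropped, mirroring the
#' caller's minimum.
#'
#' @param truth marker table with `marker_id`, `src_chr` (or `seq_id`),
#'   `src_pos` (or `start`), `label`, `inverted`.
#' @param min_block_markers minimum members per expected block.
#' @return `data.frame` with `src_chr`, `n_markers`, `orientation` and list
#'   column `marker_ids`.
#' @export
planted_block_truth <- function(truth, min_block_markers = 3L) {
  if (!"src_chr" %in% names(truth)) truth$src_chr <- truth$seq_id
  if (!"src_pos" %in% names(truth)) truth$src_pos <- truth$start
  if (!"marker_id" %in% names(truth)) truth$marker_id <- as.character(seq_len(nrow(truth)))
  truth <- truth[order(truth$src_chr, truth$src_pos), , drop = FALSE]
  runs <- list()
  for (ch in unique(truth$src_chr)) {
    sub <- truth[truth$src_chr == ch, , drop = FALSE]
    grp <- cumsum(c(TRUE, sub$label[-1L] != sub$label[-nrow(sub)]))
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      if (nrow(m) < min_block_markers) next
      runs[[length(runs) + 1L]] <- data.frame(
        src_chr = ch, n_markers = nrow(m),
        orientation = if (m$inverted[1L]) "inverted" else "collinear",
        marker_ids = I(list(m$marker_id)), stringsAsFactors = FALSE)
    }
  }
  if (!length(runs)) {
    out <- data.frame(src_chr = character(), n_markers = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
    out$marker_ids <- I(list())
    return(out)
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Simulate a shared-marker table with planted rearrangements
#'
#' Marker-level counterpart of [derive_partner_genome()]: generates marker
#' positions on a source genome, mirrors them onto a target genome, then
#' applies segmental inversions (target order reversed in place) and
#' translocations (segment appended to another target chromosome). Fast
#' ground-truth fixture for the block caller.
#'
#' @param n_chr chromosomes on each genome.
#' @param markers_per_chr markers per source chromosome.
#' @param n_inversions,n_translocations,segment_markers,context_markers as
#'   in [derive_partner_genome()].
#' @param mean_spacing mean bp between consecutive markers.
#' @param seed integer seed.
#' @return list: `shared` (input for [call_blocks()]), `truth` (marker
#'   table with `label` and `inverted`, for [planted_block_truth()]).
#' @export
simulate_shared_markers <- function(n_chr = 4L, markers_per_chr = 40L,
                                    n_inversions = 3L, n_translocations = 2L,
                                    segment_markers = 5:8,
                                    context_markers = 3L,
                                    mean_spacing = 5e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr <- paste0("W", seq_len(n_chr))
  shared <- do.call(rbind, lapply(chr, function(ch) {
    pos <- cumsum(as.integer(runif(markers_per_chr, 0.5, 1.5) * mean_spacing))
    data.frame(src_chr = ch, src_pos = pos, tgt_chr = sub("W", "T", ch),
               tgt_pos = pos, stringsAsFactors = FALSE)
  }))
  shared <- shared[order(shared$src_chr, shared$src_pos), , drop = FALSE]
  shared$marker_id <- sprintf("SM%04d", seq_len(nrow(shared)))
  rownames(shared) <- NULL
  shared$label <- "ctx"
  shared$inverted <- FALSE

  free <- lapply(chr, function(ch) {
    idx <- which(shared$src_chr == ch)
    list(c(min(idx) + context_markers, max(idx) - context_markers))
  })
  names(free) <- chr

  for (op_i in seq_len(n_inversions + n_translocations)) {
    sizes <- sample(rep(segment_markers, 2L))
    cand <- list(); sz <- NA_integer_
    for (s_try in unique(sizes)) {
      for (ch in chr) for (iv in free[[ch]]) {
        if (iv[2L] - iv[1L] + 1L >= s_try) {
          cand[[length(cand) + 1L]] <- list(chr = ch, lo = iv[1L], hi = iv[2L])
        }
      }
      if (length(cand)) { sz <- s_try; break }
    }
    if (!length(cand)) stop("not enough free markers to place all rearrangements")
    pick <- cand[[sample(length(cand), 1L)]]
    i0 <- sample(pick$lo:(pick$hi - sz + 1L), 1L)
    i1 <- i0 + sz - 1L
    free[[pick$chr]] <- c(
      Filter(function(iv) !(iv[1L] == pick$lo && iv[2L] == pick$hi), free[[pick$chr]]),
      if (i0 - pick$lo >= context_markers + 1L)
        list(c(pick$lo, i0 - context_markers - 1L)),
      if (pick$hi - i1 >= context_markers + 1L)
        list(c(i1 + context_markers + 1L, pick$hi)))
    idx <- i0:i1
    if (op_i <= n_inversions) {
      shared$tgt_pos[idx] <- rev(shared$tgt_pos[idx])
      shared$label[idx] <- paste0("inv", op_i)
      shared$inverted[idx] <- TRUE
    } else {
      dest <- sample(setdiff(unique(shared$tgt_chr), shared$tgt_chr[idx][1L]), 1L)
      base <- max(shared$tgt_pos[shared$tgt_chr == dest]) + mean_spacing
      shared$tgt_chr[idx] <- dest
      shared$tgt_pos[idx] <- base + seq_along(idx) * as.integer(mean_spacing)
      shared$label[idx] <- paste0("tra", op_i)
    }
  }
  list(shared = shared[c("marker_id", "src_chr", "src_pos", "tgt_chr", "tgt_pos")],
       truth = shared[c("marker_id", "src_chr", "src_pos", "label", "inverted")])
}

#' Simulate population-structured codominant genotypes
#'
#' Draws per-population, per-locus allele frequencies from a symmetric
#' Dirichlet (`alpha = divergence` per allele; smaller `divergence` means
#' more drift and stronger differentiation) and diploid genotypes under
#' Hardy-Weinberg equilibrium within each population. Defaults emulate a
#' two-population germplasm panel of 134 accessions scored at 32 SSR loci
#' with about five product-size alleles per locus.
#'
#' @param K number of populations.
#' @param n_per_pop accessions per population (recycled to length `K`).
#' @param n_loci loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param divergence Dirichlet concentration per allele.
#' @param missing_rate fraction of calls set missing at random.
#' @param seed integer seed.
#' @return list: `gm` ([genotype_matrix()]), `labels` (named population
#'   labels), `freqs` (list `[[pop]][[locus]]` of planted frequencies).
#' @export
simulate_genotypes <- function(K = 2L, n_per_pop = 67L, n_loci = 32L,
                               alleles_per_locus = 5L, divergence = 0.2,
                               missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 1L, alleles_per_locus >= 2L)
  n_per_pop <- rep_len(n_per_pop, K)
  n <- sum(n_per_pop)
  pop <- rep(paste0("pop", seq_len(K)), n_per_pop)
  acc <- sprintf("W%03d", seq_len(n))
  loci <- sprintf("SSR%02d", seq_len(n_loci))
  allele_labels <- as.character(seq(150L, by = 2L,
                                    length.out = alleles_per_locus))

  rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  freqs <- lapply(seq_len(K), function(p) {
    lapply(seq_len(n_loci), function(l) {
      setNames(rdirichlet1(rep(divergence, alleles_per_locus)), allele_labels)
    })
  })
  names(freqs) <- paste0("pop", seq_len(K))

  a1 <- matrix(NA_character_, n, n_loci)
  a2 <- matrix(NA_character_, n, n_loci)
  for (i in seq_len(n)) {
    p <- match(pop[i], names(freqs))
    for (l in seq_len(n_loci)) {
      pair <- sample(allele_labels, 2L, replace = TRUE, prob = freqs[[p]][[l]])
      a1[i, l] <- pair[1L]; a2[i, l] <- pair[2L]
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    a1[drop] <- NA_character_; a2[drop] <- NA_character_
  }
  list(gm = genotype_matrix(a1, a2, accessions = acc, loci = loci),
       labels = setNames(pop, acc), freqs = freqs)
}

#' Simulate replicate log-probability tables with a planted elbow
#'
#' The replicate-mean log probability of the data is piecewise linear in K
#' with a single slope break at `elbow_K` (steep improvement up to the true
#' number of populations, near-plateau beyond), plus i.i.d. Gaussian
#' replicate noise. With zero noise the Evanno statistic is infinite exactly
#' at the elbow and zero elsewhere.
#'
#' @param k_range contiguous integer K values.
#' @param elbow_K interior K where the slope breaks.
#' @param replicates runs per K.
#' @param noise_sd replicate noise standard deviation.
#' @param base_lnpd mean LnP(D) at the smallest K.
#' @param slope_before,slope_after slopes below/above the elbow.
#' @param seed integer seed.
#' @return `data.frame` with `K`, `run`, `LnPD`.
#' @export
simulate_lnpd <- function(k_range = 1:10, elbow_K = 2L, replicates = 20L,
                          noise_sd = 40, base_lnpd = -8000,
                          slope_before = 600, slope_after = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(elbow_K > min(k_range), elbow_K < max(k_range))
  mu <- base_lnpd + slope_before * (pmin(k_range, elbow_K) - min(k_range)) +
    slope_after * pmax(0, k_range - elbow_K)
  out <- expand.grid(run = seq_len(replicates), K = k_range)
  out$LnPD <- mu[match(out$K, k_range)] + rnorm(nrow(out), 0, noise_sd)
  out[c("K", "run", "LnPD")]
}
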