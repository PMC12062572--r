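# Per-site alignment feature extraction. Each reference position gets a
# 20-entry count vector: 10 channels for forward-strand reads followed by the
# same 10 for reverse-strand reads. The channels summarise the alignment
# signals the downstream classifier learns from:
#   1 depth            aligned (M/D) coverage of primary reads
#   2 del_cov          coverage by CIGAR deletions >= min_op
#   3 ins_anchor       insertion (I >= min_op) anchor sites
#   4 clip_left        left soft/hard clips >= min_clip
#   5 clip_right       right soft/hard clips >= min_clip
#   6 split_colinear   same-contig, same-strand split-read junctions
#   7 split_inverted   opposite-strand split-read junctions
#   8 split_dup        same-strand splits jumping backwards on the reference
#   9 split_interchrom inter-contig split-read junctions
#  10 low_identity     coverage by reads whose substitution rate exceeds
#                      twice the regional mean
# The channel set is isolated behind this constructor so it can be revised
# without touching the model code.

FEATURE_CHANNELS <- c("depth", "del_cov", "ins_anchor", "clip_left",
                      "clip_right", "split_colinear", "split_inverted",
                      "split_dup", "split_interchrom", "low_identity")

bam_contig_lengths <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)
  tg <- hdr[[1]]$targets
  if (is.null(tg) || length(tg) == 0L) stop("no contigs in BAM header: ", bam)
  tg
}

read_region_alignments <- function(bam, region, min_mapq) {
  which <- GenomicRanges::GRanges(region$contig,
                                  IRanges::IRanges(region$start + 1L, region$end))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "mapq"),
    tag = c("SA", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = min_mapq)
  tryCatch(
    GenomicAlignments::readGAlignments(bam, param = param),
    error = function(e) stop("cannot read BAM '", bam, "' (is it indexed?): ",
                             conditionMessage(e))
  )
}

# Estimated per-read substitution rate: (NM - indel bases) / aligned M bases.
# Reads without an NM tag fall back to the sample mean.
read_error_rates <- function(cig, nm) {
  opt <- GenomicAlignments::cigarOpTable(cig)
  mlen <- opt[, "M"]
  subs <- nm - opt[, "I"] - opt[, "D"]
  rate <- pmax(subs, 0) / pmax(mlen, 1L)
  if (anyNA(rate)) {
    fallback <- mean(rate, na.rm = TRUE)
    rate[is.na(rate)] <- if (is.nan(fallback)) 0 else fallback
  }
  rate
}

#' Extract per-site alignment features over a region
#'
#' Reads primary alignments (mapping quality at least `min_mapq`; secondary
#' and supplementary records skipped, supplementary evidence enters through
#' the SA tags of primaries) and counts, separately per strand, the 10
#' feature channels at each reference position of the region.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param region Region string (`contig:start-end`, 1-based inclusive) or a
#'   list with `contig`, `start`, `end` in 0-based half-open coordinates.
#' @param min_mapq Mapping-quality floor.
#' @param min_op Smallest CIGAR D/I operation counted as a variant event (bp).
#' @param min_clip Smallest clip counted as a clip event (bp).
#' @return An object of class `sv_feature_matrix`: list with `contig`,
#'   `start`, `end` and an integer `counts` matrix of (end - start) rows and
#'   20 columns (forward channels 1-10, reverse 11-20).
#' @export
extract_site_features <- function(bam, region, min_mapq = 20L, min_op = 30L,
                                  min_clip = 20L) {
  lens <- bam_contig_lengths(bam)
  if (is.character(region)) region <- parse_region(region, lens)
  if (!region$contig %in% names(lens)) {
    stop("contig not found in alignment file: ", region$contig)
  }
  if (region$start < 0L || region$end > lens[region$contig] ||
      region$start >= region$end) {
    stop("region out of contig bounds: ", region$contig, ":",
         region$start, "-", region$end)
  }
  span <- region$end - region$start
  counts <- matrix(0L, span, 2L * length(FEATURE_CHANNELS))
  colnames(counts) <- c(paste0("fwd_", FEATURE_CHANNELS),
                        paste0("rev_", FEATURE_CHANNELS))
  ga <- read_region_alignments(bam, region, min_mapq)
  out <- structure(list(contig = region$contig, start = region$start,
                        end = region$end, counts = counts),
                   class = "sv_feature_matrix")
  if (length(ga) == 0L) return(out)

  cig <- GenomicAlignments::cigar(ga)
  pos1 <- BiocGenerics::start(ga)
  end1 <- BiocGenerics::end(ga)
  strand_chr <- as.character(BiocGenerics::strand(ga))
  nm <- S4Vectors::mcols(ga)$NM
  sa <- S4Vectors::mcols(ga)$SA
  rate <- read_error_rates(cig, nm)
  mean_rate <- mean(rate)

  cover_vec <- function(ir) {
    if (length(ir) == 0L) return(integer(span))
    as.integer(IRanges::coverage(ir, shift = -region$start, width = span))
  }
  point_vec <- function(pos0) {
    idx <- pos0 - region$start + 1L
    idx <- idx[idx >= 1L & idx <= span]
    tabulate(idx, nbins = span)
  }

  dr_all <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = "D",
                                                              pos = pos1)
  ir_ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, ops = "I",
                                                              pos = pos1)
  ir_q <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
  opl <- GenomicAlignments::explodeCigarOpLengths(cig)
  opc <- GenomicAlignments::explodeCigarOps(cig)
  first_op <- vapply(opc, function(x) x[1L], "")
  last_op <- vapply(opc, function(x) x[length(x)], "")
  first_len <- vapply(opl, function(x) x[1L], 0L)
  last_len <- vapply(opl, function(x) x[length(x)], 0L)

  for (s in c("+", "-")) {
    sel <- strand_chr == s
    if (!any(sel)) next
    off <- if (s == "+") 0L else length(FEATURE_CHANNELS)
    ch <- function(i) i + off
    counts[, ch(1L)] <- counts[, ch(1L)] +
      cover_vec(IRanges::IRanges(pos1[sel], end1[sel]))
    dr <- unlist(dr_all[sel], use.names = FALSE)
    dr <- dr[IRanges::width(dr) >= min_op]
    counts[, ch(2L)] <- counts[, ch(2L)] + cover_vec(dr)
    anc <- unlist(ir_ref[sel], use.names = FALSE)
    ilen <- unlist(IRanges::width(ir_q[sel]), use.names = FALSE)
    counts[, ch(3L)] <- counts[, ch(3L)] +
      point_vec(BiocGenerics::start(anc)[ilen >= min_op] - 1L)
    lc <- sel & first_op %in% c("S", "H") & first_len >= min_clip
    counts[, ch(4L)] <- counts[, ch(4L)] + point_vec(pos1[lc] - 1L)
    rc <- sel & last_op %in% c("S", "H") & last_len >= min_clip
    counts[, ch(5L)] <- counts[, ch(5L)] + point_vec(end1[rc])
    lowid <- sel & mean_rate > 0 & rate > 2 * mean_rate
    if (any(lowid)) {
      counts[, ch(10L)] <- counts[, ch(10L)] +
        cover_vec(IRanges::IRanges(pos1[lowid], end1[lowid]))
    }
  }

  # split-read channels from the SA tags of primary records
  has_sa <- which(!is.na(sa) & !is.null(sa) & sa != "")
  for (i in has_sa) {
    prim <- segment_from_alignment(region$contig, pos1[i] - 1L, strand_chr[i],
                                   cig[i])
    segs <- parse_sa_tag(sa[i])
    for (j in seq_len(nrow(segs))) {
      supp <- segment_from_alignment(segs$contig[j], segs$pos[j],
                                     segs$strand[j], segs$cigar[j])
      pr <- classify_segment_pair(prim, supp)
      if (is.null(pr)) next
      off <- if (strand_chr[i] == "+") 0L else length(FEATURE_CHANNELS)
      chan <- switch(pr$kind, colinear = 6L, inverted = 7L, dup = 8L,
                     interchrom = 9L, NULL)
      if (is.null(chan)) next
      v <- point_vec(pr$junction_primary)
      counts[, chan + off] <- counts[, chan + off] + v
    }
  }

  out$counts <- counts
  out
}

#' Mean aligned coverage of a feature matrix
#'
#' @param fm An `sv_feature_matrix`.
#' @return Mean depth (forward + reverse) over the region.
#' @export
feature_coverage <- function(fm) {
  mean(fm$counts[, 1L] + fm$counts[, length(FEATURE_CHANNELS) + 1L])
}

# ---- window tiling ---------------------------------------------------------

#' Tile a feature matrix into consecutive 2000 bp window batches
#'
#' Windows are non-overlapping and cover every position exactly once; a
#' trailing partial window is zero-padded, with fully padded 200 bp
#' submatrices flagged in the pad mask.
#'
#' @param fm An `sv_feature_matrix`.
#' @return An object of class `sv_window_set`; use [get_window_batch()] to
#'   materialise individual windows.
#' @export
tile_windows <- function(fm) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  span <- fm$end - fm$start
  n <- if (span == 0L) 0L else as.integer(ceiling(span / WINDOW_LEN))
  starts <- fm$start + (seq_len(n) - 1L) * WINDOW_LEN
  structure(list(contig = fm$contig, start = fm$start, end = fm$end,
                 counts = fm$counts,
                 windows = data.frame(start = starts)),
            class = "sv_window_set")
}

#' Materialise one window batch from a window set
#'
#' @param ws An `sv_window_set`.
#' @param i Window index.
#' @return List with `contig`, `start`, `x` (2000 x 20 numeric matrix,
#'   zero-padded past the end of the data) and `pad_mask` (logical length 10,
#'   TRUE for submatrices that lie entirely beyond the data).
#' @export
get_window_batch <- function(ws, i) {
  stopifnot(inherits(ws, "sv_window_set"), i >= 1L, i <= nrow(ws$windows))
  w0 <- ws$windows$start[i]
  x <- matrix(0, WINDOW_LEN, ncol(ws$counts))
  avail <- min(WINDOW_LEN, ws$end - w0)
  if (avail > 0L) {
    r0 <- w0 - ws$start
    x[seq_len(avail), ] <- ws$counts[(r0 + 1L):(r0 + avail), , drop = FALSE]
  }
  sub_starts <- w0 + (seq_len(SUBS_PER_WINDOW) - 1L) * SUB_LEN
  list(contig = ws$contig, start = w0, x = x, pad_mask = sub_starts >= ws$end)
}

# Stack selected windows into a ((n*2000) x 20) numeric matrix.
materialize_windows <- function(ws, idx) {
  x <- matrix(0, length(idx) * WINDOW_LEN, ncol(ws$counts))
  for (k in seq_along(idx)) {
    b <- get_window_batch(ws, idx[k])
    x[((k - 1L) * WINDOW_LEN + 1L):(k * WINDOW_LEN), ] <- b$x
  }
  x
}

pad_mask_matrix <- function(ws, idx) {
  sub_starts <- outer(ws$windows$start[idx],
                      (seq_len(SUBS_PER_WINDOW) - 1L) * SUB_LEN, "+")
  sub_starts >= ws$end
}

# ---- training container ----------------------------------------------------

#' Assemble a training set from labelled window sets
#'
#' @param window_sets List of `sv_window_set` objects (e.g. one per contig).
#' @param labels List of 0/1 label matrices (windows x 10), aligned with
#'   `window_sets`; see [label_windows()].
#' @param coverage Global mean coverage used to normalise counts before they
#'   enter the network.
#' @return An object of class `sv_training_set`.
#' @export
build_training_set <- function(window_sets, labels, coverage) {
  stopifnot(length(window_sets) == length(labels), coverage > 0)
  for (k in seq_along(window_sets)) {
    stopifnot(inherits(window_sets[[k]], "sv_window_set"),
              nrow(labels[[k]]) == nrow(window_sets[[k]]$windows))
  }
  index <- do.call(rbind, lapply(seq_along(window_sets), function(k) {
    data.frame(set = k, win = seq_len(nrow(window_sets[[k]]$windows)))
  }))
  structure(list(sets = window_sets, labels = labels, coverage = coverage,
                 index = index),
            class = "sv_training_set")
}

training_batch <- function(ts, rows) {
  n <- length(rows)
  x <- matrix(0, n * WINDOW_LEN, 2L * length(FEATURE_CHANNELS))
  y <- numeric(n * SUBS_PER_WINDOW)
  valid <- logical(n * SUBS_PER_WINDOW)
  for (k in seq_len(n)) {
    set_i <- ts$index$set[rows[k]]
    win_i <- ts$index$win[rows[k]]
    b <- get_window_batch(ts$sets[[set_i]], win_i)
    x[((k - 1L) * WINDOW_LEN + 1L):(k * WINDOW_LEN), ] <- b$x
    sl <- ((k - 1L) * SUBS_PER_WINDOW + 1L):(k * SUBS_PER_WINDOW)
    y[sl] <- ts$labels[[set_i]][win_i, ]
    valid[sl] <- !b$pad_mask
  }
  list(x = x / ts$coverage, y = y, valid = valid)
}

training_labels <- function(ts) {
  unlist(lapply(seq_len(nrow(ts$index)), function(r) {
    ts$labels[[ts$index$set[r]]][ts$index$win[r], ]
  }), use.names = FALSE)
}

training_pad <- function(ts) {
  unlist(lapply(seq_len(nrow(ts$index)), function(r) {
    ws <- ts$sets[[ts$index$set[r]]]
    pad_mask_matrix(ws, ts$index$win[r])[1L, ]
  }), use.names = FALSE)
}
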