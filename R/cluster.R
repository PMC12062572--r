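# Breakpoint clustering. Signatures of one SV type on one contig are grouped
# by mean-shift over their breakpoint positions under a Gaussian KDE whose
# bandwidth depends on the SV type and the sample's mean read error rate;
# clusters are then refined into subclusters of similar length using the
# median-length rule. Breakend (BND) signatures are paired positionally.

#' Clustering configuration
#'
#' Bandwidths are the KDE kernel scales (bp) used by mean shift, per SV type;
#' when the mean read error rate is below `high_quality_error_cutoff` the
#' larger `high_quality_bandwidth` is used for all types so that sparse,
#' precise signals are gathered over a broader range.
#'
#' @param bandwidth_del,bandwidth_ins,bandwidth_dup,bandwidth_inv Per-type
#'   bandwidths (bp).
#' @param high_quality_bandwidth Bandwidth (bp) for low-error samples.
#' @param high_quality_error_cutoff Mean substitution-rate threshold below
#'   which reads count as high quality.
#' @param length_ratio Subcluster refinement threshold ratio in (0, 1].
#' @param tra_tolerance Positional tolerance (bp) when pairing breakends.
#' @return List of class `sv_cluster_config`.
#' @export
cluster_config <- function(bandwidth_del = 1000L, bandwidth_ins = 300L,
                           bandwidth_dup = 500L, bandwidth_inv = 500L,
                           high_quality_bandwidth = 1500L,
                           high_quality_error_cutoff = 0.10,
                           length_ratio = 0.7, tra_tolerance = 1000L) {
  stopifnot(bandwidth_del > 0, bandwidth_ins > 0, bandwidth_dup > 0,
            bandwidth_inv > 0, high_quality_bandwidth > 0,
            length_ratio > 0, length_ratio <= 1)
  structure(list(bandwidth_del = bandwidth_del, bandwidth_ins = bandwidth_ins,
                 bandwidth_dup = bandwidth_dup, bandwidth_inv = bandwidth_inv,
                 high_quality_bandwidth = high_quality_bandwidth,
                 high_quality_error_cutoff = high_quality_error_cutoff,
                 length_ratio = length_ratio, tra_tolerance = tra_tolerance),
            class = "sv_cluster_config")
}

#' Select the mean-shift bandwidth for an SV type
#'
#' Returns the per-type default (DEL 1000, INS 300, DUP 500, INV 500 bp), or
#' `high_quality_bandwidth` (1500 bp) when the mean read error rate is below
#' the high-quality cutoff. Breakends are clustered positionally, not by
#' density, so BND is rejected.
#'
#' @param svtype One of "DEL", "INS", "DUP", "INV".
#' @param mean_error_rate Mean per-read substitution-rate estimate.
#' @param config A [cluster_config()].
#' @return Bandwidth in bp.
#' @export
select_bandwidth <- function(svtype, mean_error_rate,
                             config = cluster_config()) {
  if (!svtype %in% c("DEL", "INS", "DUP", "INV")) {
    stop("no density bandwidth for svtype '", svtype,
         "'; breakends are paired positionally")
  }
  if (mean_error_rate < config$high_quality_error_cutoff) {
    return(config$high_quality_bandwidth)
  }
  switch(svtype,
         DEL = config$bandwidth_del,
         INS = config$bandwidth_ins,
         DUP = config$bandwidth_dup,
         INV = config$bandwidth_inv)
}

#' Mean-shift clustering of breakpoint positions
#'
#' Each point ascends the Gaussian kernel density estimate (bandwidth `h`)
#' by iterated weighted means until convergence; points whose trajectories
#' converge to modes closer than
#' `h / 2` share a cluster (ties broken toward the smaller coordinate).
#'
#' @param positions Numeric vector of breakpoint positions.
#' @param bandwidth Kernel scale in bp (> 0).
#' @param tol Convergence tolerance (bp); small enough that trajectories on
#'   near-flat density plateaus still reach their mode.
#' @param max_iter Iteration cap.
#' @return List with `assignment` (cluster index per input point, clusters
#'   numbered by ascending mode) and `modes` (numeric vector of cluster
#'   modes).
#' @export
mean_shift <- function(positions, bandwidth, tol = 1e-3, max_iter = 5000L) {
  stopifnot(bandwidth > 0)
  n <- length(positions)
  if (n == 0L) return(list(assignment = integer(0), modes = numeric(0)))
  x <- as.numeric(positions)
  p <- as.numeric(positions)
  h2 <- bandwidth^2
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, p, "-")^2
    w <- exp(-d2 / (2 * h2))
    xn <- as.vector(w %*% p) / rowSums(w)
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  ord <- order(x)
  modes <- x[ord]
  cluster_of <- integer(n)
  cid <- 1L
  anchor <- modes[1L]
  cluster_of[ord[1L]] <- 1L
  for (k in seq_len(n)[-1L]) {
    if (modes[k] - anchor > bandwidth / 2) {
      cid <- cid + 1L
      anchor <- modes[k]
    }
    cluster_of[ord[k]] <- cid
  }
  mode_pos <- vapply(seq_len(cid), function(c) stats::median(x[cluster_of == c]), 0)
  list(assignment = cluster_of, modes = mode_pos)
}

#' Refine a cluster into subclusters of similar length
#'
#' Members are sorted by ascending length; a new subcluster opens whenever a
#' member's length differs from the first (shortest) member of the open
#' subcluster by at least `median(length) * length_ratio`.
#'
#' @param lengths Numeric vector of member SV lengths (> 0).
#' @param length_ratio Threshold ratio in (0, 1].
#' @return Integer vector assigning each input length to a subcluster
#'   (numbered in ascending length order).
#' @export
refine_by_length <- function(lengths, length_ratio = 0.7) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  med <- stats::median(lengths)
  thr <- med * length_ratio
  ord <- order(lengths)
  sub <- integer(n)
  cid <- 1L
  first_len <- lengths[ord[1L]]
  sub[ord[1L]] <- 1L
  for (k in seq_len(n)[-1L]) {
    if (lengths[ord[k]] - first_len >= thr) {
      cid <- cid + 1L
      first_len <- lengths[ord[k]]
    }
    sub[ord[k]] <- cid
  }
  sub
}

#' Pair breakend signatures into translocation clusters
#'
#' Breakends are normalised so the lexicographically smaller (contig,
#' position) end comes first; two breakends share a cluster iff both ends lie
#' on the same contig pair and both positional differences are within
#' `tra_tolerance` of the cluster's founding member.
#'
#' @param bnds data.frame of BND signatures (columns contig, pos,
#'   mate_contig, mate_pos, read, error_rate).
#' @param tra_tolerance Positional tolerance in bp.
#' @return List of clusters, each a list with `contig`, `pos`, `mate_contig`,
#'   `mate_pos` (medians of the member ends) and `members` (row data.frame).
#' @export
pair_translocations <- function(bnds, tra_tolerance = 1000L) {
  if (is.null(bnds) || nrow(bnds) == 0L) return(list())
  flip <- (bnds$mate_contig < bnds$contig) |
    (bnds$mate_contig == bnds$contig & bnds$mate_pos < bnds$pos)
  c1 <- ifelse(flip, bnds$mate_contig, bnds$contig)
  p1 <- ifelse(flip, bnds$mate_pos, bnds$pos)
  c2 <- ifelse(flip, bnds$contig, bnds$mate_contig)
  p2 <- ifelse(flip, bnds$pos, bnds$mate_pos)
  ord <- order(c1, c2, p1, p2)
  clusters <- list()
  open <- list()   # per contig-pair: founding p1/p2 and member indices
  for (i in ord) {
    keypair <- paste(c1[i], c2[i], sep = "\r")
    placed <- FALSE
    if (!is.null(open[[keypair]])) {
      for (k in seq_along(open[[keypair]])) {
        cl <- open[[keypair]][[k]]
        if (abs(p1[i] - cl$p1) <= tra_tolerance &&
            abs(p2[i] - cl$p2) <= tra_tolerance) {
          open[[keypair]][[k]]$idx <- c(cl$idx, i)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      open[[keypair]] <- c(open[[keypair]],
                           list(list(p1 = p1[i], p2 = p2[i], idx = i)))
    }
  }
  for (keypair in names(open)) {
    for (cl in open[[keypair]]) {
      idx <- cl$idx
      clusters[[length(clusters) + 1L]] <- list(
        contig = c1[idx[1L]],
        pos = as.integer(round(stats::median(p1[idx]))),
        mate_contig = c2[idx[1L]],
        mate_pos = as.integer(round(stats::median(p2[idx]))),
        members = bnds[idx, , drop = FALSE])
    }
  }
  clusters
}

#' Cluster extracted signatures into candidate SV events
#'
#' Intra-contig types (DEL/INS/DUP/INV) are mean-shift clustered per contig
#' with the type- and error-rate-dependent bandwidth, then refined by the
#' median-length rule; breakends are paired positionally.
#'
#' @param sigs Signature data.frame from [extract_signatures()].
#' @param config A [cluster_config()].
#' @return List of subcluster records: each has `svtype`, `contig`, `pos`
#'   (mode of member breakpoints), `len` (median member length), `members`
#'   (signature rows), and for TRA additionally `mate_contig`, `mate_pos`.
#' @export
cluster_signatures <- function(sigs, config = cluster_config()) {
  out <- list()
  if (is.null(sigs) || nrow(sigs) == 0L) return(out)
  mean_err <- mean(sigs$error_rate, na.rm = TRUE)
  for (tp in c("DEL", "INS", "DUP", "INV")) {
    st <- sigs[sigs$svtype == tp, , drop = FALSE]
    if (nrow(st) == 0L) next
    bw <- select_bandwidth(tp, mean_err, config)
    for (ctg in sort(unique(st$contig))) {
      sc <- st[st$contig == ctg, , drop = FALSE]
      ms <- mean_shift(sc$pos, bw)
      for (ci in seq_along(ms$modes)) {
        mem <- sc[ms$assignment == ci, , drop = FALSE]
        sub <- refine_by_length(mem$len, config$length_ratio)
        for (si in sort(unique(sub))) {
          mm <- mem[sub == si, , drop = FALSE]
          out[[length(out) + 1L]] <- list(
            svtype = tp, contig = ctg,
            pos = as.integer(round(stats::median(mm$pos))),
            len = as.integer(round(stats::median(mm$len))),
            members = mm)
        }
      }
    }
  }
  bnds <- sigs[sigs$svtype == "BND", , drop = FALSE]
  for (cl in pair_translocations(bnds, config$tra_tolerance)) {
    out[[length(out) + 1L]] <- list(
      svtype = "TRA", contig = cl$contig, pos = cl$pos, len = 0L,
      mate_contig = cl$mate_contig, mate_pos = cl$mate_pos,
      members = cl$members)
  }
  out
}
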