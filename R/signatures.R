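# Read-level SV signature extraction inside candidate regions. Two sources:
# intra-alignment CIGAR D/I operations, and split reads reconstructed from a
# primary record plus its SA tag. All coordinates are 0-based half-open.

#' Parse an SA tag into its alignment segments
#'
#' @param sa SA tag string (`rname,pos,strand,CIGAR,mapQ,NM;` repeated).
#' @return data.frame with columns `contig`, `pos` (0-based), `strand`,
#'   `cigar`, `mapq`, `nm`.
#' @export
parse_sa_tag <- function(sa) {
  parts <- strsplit(strsplit(sa, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  parts <- parts[lengths(parts) >= 6L]
  data.frame(
    contig = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)) - 1L,
    strand = vapply(parts, `[`, "", 3L),
    cigar = vapply(parts, `[`, "", 4L),
    mapq = as.integer(vapply(parts, `[`, "", 5L)),
    nm = as.integer(vapply(parts, `[`, "", 6L)),
    stringsAsFactors = FALSE
  )
}

# One alignment segment of a read, with read-interval coordinates expressed
# in the original (as-sequenced) read orientation: for a reverse-strand
# record the stored sequence is the reverse complement, so its leading clip
# sits at the *end* of the original read.
segment_from_alignment <- function(contig, pos0, strand, cigar) {
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qal <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                                      after.soft.clipping = TRUE)
  opc <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  opl <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  left <- if (opc[1L] %in% c("S", "H")) opl[1L] else 0L
  right <- if (opc[length(opc)] %in% c("S", "H")) opl[length(opl)] else 0L
  qs <- if (strand == "+") left else right
  list(contig = contig, rs = pos0, re = pos0 + rw, strand = strand,
       qs = qs, qe = qs + qal)
}

# Classify the relationship between two alignment segments of one read.
# Returns NULL when the pair is uninformative, otherwise a list with `kind`
# (colinear / dup / inverted / interchrom), junction coordinates j1/j2 on the
# two segments (read-order), reference/read gaps for colinear pairs, and
# `junction_primary`, the junction coordinate on the side of segment `a`.
classify_segment_pair <- function(a, b, dup_min = 30L) {
  swapped <- b$qs < a$qs
  s1 <- if (swapped) b else a
  s2 <- if (swapped) a else b
  jcoord <- function(seg, at_end) {
    if (at_end) { if (seg$strand == "+") seg$re else seg$rs }
    else { if (seg$strand == "+") seg$rs else seg$re }
  }
  j1 <- jcoord(s1, at_end = TRUE)    # read-trailing end of the first segment
  j2 <- jcoord(s2, at_end = FALSE)   # read-leading end of the second segment
  readgap <- s2$qs - s1$qe
  if (s1$contig != s2$contig) {
    kind <- "interchrom"; refgap <- NA_integer_
  } else if (s1$strand != s2$strand) {
    kind <- "inverted"; refgap <- NA_integer_
  } else {
    # mirror a -/- pair into ++ semantics (read order reverses on the
    # reverse-complemented read, reference order is unchanged)
    if (s1$strand == "-") {
      refgap <- s1$rs - s2$re
      dup_pos <- s1$rs
      dup_len <- s2$re - s1$rs
    } else {
      refgap <- s2$rs - s1$re
      dup_pos <- s2$rs
      dup_len <- s1$re - s2$rs
    }
    kind <- if (refgap <= -dup_min) "dup" else "colinear"
  }
  out <- list(kind = kind, j1 = j1, j2 = j2, refgap = refgap,
              readgap = readgap, seg1 = s1, seg2 = s2,
              junction_primary = if (swapped) j2 else j1)
  if (kind == "dup") { out$dup_pos <- dup_pos; out$dup_len <- dup_len }
  out
}

sig_row <- function(svtype, contig, pos, len, read, error_rate,
                    mate_contig = NA_character_, mate_pos = NA_integer_) {
  data.frame(svtype = svtype, contig = contig, pos = as.integer(pos),
             len = as.integer(len), mate_contig = mate_contig,
             mate_pos = as.integer(mate_pos), read = read,
             error_rate = error_rate, stringsAsFactors = FALSE)
}

empty_signatures <- function() {
  data.frame(svtype = character(0), contig = character(0), pos = integer(0),
             len = integer(0), mate_contig = character(0),
             mate_pos = integer(0), read = character(0),
             error_rate = numeric(0), stringsAsFactors = FALSE)
}

#' Extract DEL/INS signatures from one CIGAR string
#'
#' Each deletion (D) operation of at least `min_sv_candidate` bases yields a
#' DEL signature at its reference interval; each insertion (I) operation of
#' at least `min_sv_candidate` bases yields an INS signature anchored at its
#' reference position.
#'
#' @param contig,pos0 Alignment contig and 0-based start.
#' @param cigar CIGAR string of a primary alignment.
#' @param read Read name carried into the signatures.
#' @param error_rate Per-read substitution-rate estimate.
#' @param min_sv_candidate Minimum operation length (bp).
#' @return data.frame of signatures (possibly empty).
#' @export
signatures_from_cigar <- function(contig, pos0, cigar, read = "",
                                  error_rate = 0, min_sv_candidate = 30L) {
  opc <- tryCatch(GenomicAlignments::explodeCigarOps(cigar)[[1]],
                  error = function(e) NULL)
  if (is.null(opc)) {
    warning("skipping malformed CIGAR for read ", read)
    return(empty_signatures())
  }
  opl <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refoff <- c(0L, cumsum(ifelse(opc %in% c("M", "D", "N", "=", "X"), opl, 0L)))
  rows <- list()
  for (i in seq_along(opc)) {
    if (opl[i] < min_sv_candidate) next
    if (opc[i] == "D") {
      rows[[length(rows) + 1L]] <-
        sig_row("DEL", contig, pos0 + refoff[i], opl[i], read, error_rate)
    } else if (opc[i] == "I") {
      rows[[length(rows) + 1L]] <-
        sig_row("INS", contig, pos0 + refoff[i], opl[i], read, error_rate)
    }
  }
  if (length(rows) == 0L) empty_signatures() else do.call(rbind, rows)
}

#' Extract SV signatures from the split alignments of one read
#'
#' Adjacent segment pairs (ordered along the read) are classified: same
#' contig and strand with a reference gap of at least `min_sv_candidate`
#' gives a DEL; an unaligned read gap of at least `min_sv_candidate` with a
#' near-zero reference gap gives an INS; a backward reference jump gives a
#' DUP of the overlapped span; opposite strands give an INV spanning the two
#' junctions; different contigs give a BND.
#'
#' @param segments List of segments from [segment_from_alignment()].
#' @param read,error_rate Read name and substitution-rate estimate.
#' @param min_sv_candidate Minimum signature length (bp).
#' @param junction_slack Read/reference gap (bp) ignored as sequencing noise
#'   when classifying junctions.
#' @return data.frame of signatures (empty for single-segment input).
#' @export
signatures_from_splits <- function(segments, read = "", error_rate = 0,
                                   min_sv_candidate = 30L,
                                   junction_slack = 100L) {
  if (length(segments) < 2L) return(empty_signatures())
  qs <- vapply(segments, function(s) s$qs, 0L)
  segments <- segments[order(qs)]
  rows <- list()
  for (i in seq_len(length(segments) - 1L)) {
    pr <- classify_segment_pair(segments[[i]], segments[[i + 1L]],
                                dup_min = min_sv_candidate)
    if (is.null(pr)) next
    s1 <- pr$seg1; s2 <- pr$seg2
    if (pr$kind == "interchrom") {
      rows[[length(rows) + 1L]] <-
        sig_row("BND", s1$contig, pr$j1, 0L, read, error_rate,
                mate_contig = s2$contig, mate_pos = pr$j2)
    } else if (pr$kind == "inverted") {
      len <- abs(pr$j2 - pr$j1)
      if (len >= min_sv_candidate) {
        rows[[length(rows) + 1L]] <-
          sig_row("INV", s1$contig, min(pr$j1, pr$j2), len, read, error_rate)
      }
    } else if (pr$kind == "dup") {
      if (pr$dup_len >= min_sv_candidate) {
        rows[[length(rows) + 1L]] <-
          sig_row("DUP", s1$contig, pr$dup_pos, pr$dup_len, read, error_rate)
      }
    } else {
      if (pr$refgap >= min_sv_candidate) {
        rows[[length(rows) + 1L]] <-
          sig_row("DEL", s1$contig, min(pr$j1, pr$j2), pr$refgap, read,
                  error_rate)
      } else if (pr$readgap >= min_sv_candidate &&
                 abs(pr$refgap) <= junction_slack) {
        rows[[length(rows) + 1L]] <-
          sig_row("INS", s1$contig, min(pr$j1, pr$j2), pr$readgap, read,
                  error_rate)
      }
    }
  }
  if (length(rows) == 0L) empty_signatures() else do.call(rbind, rows)
}

#' Extract all read-level signatures within candidate regions
#'
#' Re-scans primary alignments overlapping the (merged) candidate regions and
#' collects CIGAR and split-read signatures. Duplicate signatures from
#' overlapping regions are removed; extraction is deterministic and
#' order-invariant.
#'
#' @param bam Indexed BAM path.
#' @param regions data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. from [candidate_regions()].
#' @param min_mapq Mapping-quality floor.
#' @param min_sv_candidate Minimum signature length (bp).
#' @param junction_slack See [signatures_from_splits()].
#' @return data.frame of signatures with columns svtype, contig, pos, len,
#'   mate_contig, mate_pos, read, error_rate.
#' @export
extract_signatures <- function(bam, regions, min_mapq = 20L,
                               min_sv_candidate = 30L, junction_slack = 100L) {
  if (nrow(regions) == 0L) return(empty_signatures())
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end)))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("qname", "flag", "mapq"),
    tag = c("SA", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = min_mapq)
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) return(empty_signatures())
  cig <- GenomicAlignments::cigar(ga)
  pos1 <- BiocGenerics::start(ga)
  strand_chr <- as.character(BiocGenerics::strand(ga))
  contig <- as.character(GenomicAlignments::seqnames(ga))
  qname <- S4Vectors::mcols(ga)$qname
  nm <- S4Vectors::mcols(ga)$NM
  sa <- S4Vectors::mcols(ga)$SA
  # drop records duplicated across query ranges
  key <- paste(qname, contig, pos1, cig, sep = "\r")
  keep <- !duplicated(key)
  rate <- read_error_rates(cig, nm)
  out <- list()
  for (i in which(keep)) {
    out[[length(out) + 1L]] <-
      signatures_from_cigar(contig[i], pos1[i] - 1L, cig[i], qname[i],
                            rate[i], min_sv_candidate)
    if (!is.na(sa[i]) && nzchar(sa[i])) {
      segs <- parse_sa_tag(sa[i])
      seglist <- c(
        list(segment_from_alignment(contig[i], pos1[i] - 1L, strand_chr[i],
                                    cig[i])),
        lapply(seq_len(nrow(segs)), function(j) {
          segment_from_alignment(segs$contig[j], segs$pos[j], segs$strand[j],
                                 segs$cigar[j])
        }))
      out[[length(out) + 1L]] <-
        signatures_from_splits(seglist, qname[i], rate[i], min_sv_candidate,
                               junction_slack)
    }
  }
  sigs <- do.call(rbind, out)
  if (is.null(sigs) || nrow(sigs) == 0L) return(empty_signatures())
  sigs <- sigs[!duplicated(paste(sigs$read, sigs$svtype, sigs$contig,
                                 sigs$pos, sigs$len, sigs$mate_contig,
                                 sigs$mate_pos, sep = "\r")), , drop = FALSE]
  rownames(sigs) <- NULL
  sigs
}
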