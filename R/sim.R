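# Synthetic-data generator: random reference contigs, diploid SV implantation
# and analytically constructed long-read alignments written as sorted,
# indexed BAM. No external aligner is involved: each read's CIGAR and split
# segments are derived exactly from the implanted variants, which makes the
# generator fully deterministic per seed and gives the test bed exact truth.
#
# Donor haplotypes are represented as block lists over the reference
# (oriented reference spans plus novel insertions); a read is an interval on
# the donor that is walked through the blocks to obtain its alignment
# segments. Sequencing error is modelled as substitutions at the configured
# per-read rate, reflected in the NM tags.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

#' Simulation configuration
#'
#' Defaults describe the package's standard benchmark: two 1 Mb contigs, 20
#' SVs of each type of 60-2000 bp (translocations are breakend junctions; 20
#' junctions = 10 inserted-segment events), half the variants heterozygous,
#' 30x coverage of ~10 kb reads with a 10% substitution error rate.
#'
#' @param ref_length Length of each contig (bp).
#' @param n_contigs Number of contigs (>= 2 when translocations requested).
#' @param n_sv Named counts per type (DEL, INS, DUP, INV, TRA); the TRA count
#'   is in junctions and must be even.
#' @param sv_size Length range (bp) for DEL/INS/DUP/INV.
#' @param het_fraction Fraction of variants implanted heterozygously.
#' @param coverage Total haploid-summed coverage (x).
#' @param read_length_mean,read_length_sd,min_read_length Read length model (bp).
#' @param error_rate Per-base substitution rate in [0, 0.5).
#' @param tra_insert_size Range (bp) of the translocated segment.
#' @param seed Integer seed governing every random choice.
#' @return List of class `sv_sim_config`.
#' @export
sim_config <- function(ref_length = 1000000L, n_contigs = 2L,
                       n_sv = c(DEL = 20L, INS = 20L, DUP = 20L, INV = 20L,
                                TRA = 20L),
                       sv_size = c(60L, 2000L), het_fraction = 0.5,
                       coverage = 30, read_length_mean = 10000L,
                       read_length_sd = 2000L, min_read_length = 500L,
                       error_rate = 0.10, tra_insert_size = c(2000L, 5000L),
                       seed = 1L) {
  n_sv <- n_sv[c("DEL", "INS", "DUP", "INV", "TRA")]
  n_sv[is.na(n_sv)] <- 0L
  names(n_sv) <- c("DEL", "INS", "DUP", "INV", "TRA")
  stopifnot(ref_length >= 10000L, coverage > 0, het_fraction >= 0,
            het_fraction <= 1, error_rate >= 0, error_rate < 0.5,
            n_sv[["TRA"]] %% 2L == 0L)
  if (n_sv[["TRA"]] > 0L && n_contigs < 2L) {
    stop("translocations need at least 2 contigs")
  }
  structure(list(ref_length = as.integer(ref_length),
                 n_contigs = as.integer(n_contigs), n_sv = n_sv,
                 sv_size = as.integer(sv_size), het_fraction = het_fraction,
                 coverage = coverage,
                 read_length_mean = as.integer(read_length_mean),
                 read_length_sd = as.integer(read_length_sd),
                 min_read_length = as.integer(min_read_length),
                 error_rate = error_rate,
                 tra_insert_size = as.integer(tra_insert_size),
                 seed = as.integer(seed)),
            class = "sv_sim_config")
}

#' Simulate a random reference
#'
#' Uniform-random A/C/G/T sequence, deterministic per seed.
#'
#' @param length Contig length (bp), at least 10 kb.
#' @param seed Integer seed.
#' @param n_contigs Number of contigs (named ctg1, ctg2, ...).
#' @return A `DNAStringSet`.
#' @export
simulate_reference <- function(length, seed = 1L, n_contigs = 1L) {
  stopifnot(length >= 10000L)
  set.seed(seed)
  seqs <- vapply(seq_len(n_contigs), function(i) random_dna(length), "")
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  Biostrings::DNAStringSet(seqs)
}

# Reserve non-overlapping placement slots on one contig. Intervals of up to
# `span_max` bp starting at the returned 0-based offsets are separated by at
# least `spacing` bp.
place_slots <- function(contig_len, n, span_max, spacing, jitter_max) {
  margin <- 5000L
  slot <- span_max + spacing + jitter_max
  avail <- contig_len - 2L * margin
  n_slots <- avail %/% slot
  if (n_slots < n) {
    stop("contig too short for the requested variant load (need ", n,
         " slots of ", slot, " bp)")
  }
  picks <- sort(sample.int(n_slots, n))
  margin + (picks - 1L) * slot + sample.int(jitter_max, n, replace = TRUE)
}

#' Implant structural variants into a reference
#'
#' Builds diploid donor haplotypes as block lists over the reference.
#' Heterozygous variants go to one random haplotype, homozygous ones to both.
#' Translocations are inter-contig segment insertions; each event records its
#' two junctions as two TRA truth entries.
#'
#' @param reference `DNAStringSet` or named character vector of contigs.
#' @param config An [sim_config()]. The caller is responsible for seeding.
#' @return List of class `sv_donor` with `ref` (named character), `truth`
#'   (data.frame: svtype, contig, pos, end, len, genotype, hap, mate_contig,
#'   mate_pos) and `blocks` (`blocks[[contig]][[hap]]` data.frames).
#' @export
implant_svs <- function(reference, config) {
  ref <- if (inherits(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else reference
  ctgs <- names(ref)
  stopifnot(length(ctgs) >= 1L)
  max_size <- max(config$sv_size[2L], config$tra_insert_size[2L])
  n_tra_events <- config$n_sv[["TRA"]] %/% 2L

  # assign intra-contig events round-robin over contigs
  ev <- list()
  for (tp in c("DEL", "INS", "DUP", "INV")) {
    k <- config$n_sv[[tp]]
    if (k == 0L) next
    ev[[tp]] <- data.frame(svtype = tp,
                           contig = ctgs[((seq_len(k) - 1L) %% length(ctgs)) + 1L],
                           len = resample(config$sv_size[1L]:config$sv_size[2L], k),
                           stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(svtype = character(0), contig = character(0),
                         len = integer(0), stringsAsFactors = FALSE)
  }
  tra <- NULL
  if (n_tra_events > 0L) {
    host <- ctgs[((seq_len(n_tra_events) - 1L) %% length(ctgs)) + 1L]
    src <- ctgs[(match(host, ctgs) %% length(ctgs)) + 1L]
    tra <- data.frame(svtype = "TRA", contig = host, src_contig = src,
                      len = resample(config$tra_insert_size[1L]:config$tra_insert_size[2L],
                                     n_tra_events),
                      stringsAsFactors = FALSE)
  }

  # reserve slots per contig: intra-SV spans, TRA host anchors, TRA sources
  need <- table(factor(events$contig, levels = ctgs)) +
    (if (is.null(tra)) 0L else table(factor(tra$contig, levels = ctgs))) +
    (if (is.null(tra)) 0L else table(factor(tra$src_contig, levels = ctgs)))
  pos_pool <- list()
  spacing <- 2L * config$sv_size[2L]
  for (cg in ctgs) {
    k <- as.integer(need[[cg]])
    pos_pool[[cg]] <- if (k > 0L) {
      as.list(place_slots(nchar(ref[[cg]]), k, max_size, spacing,
                          config$sv_size[2L]))
    } else list()
  }
  take <- function(cg) {
    p <- pos_pool[[cg]][[1L]]
    pos_pool[[cg]] <<- pos_pool[[cg]][-1L]
    p
  }

  truth <- list(); svlist <- list()
  add_sv <- function(row) svlist[[length(svlist) + 1L]] <<- row
  n_all <- nrow(events) + (if (is.null(tra)) 0L else nrow(tra))
  is_het <- stats::runif(n_all) < config$het_fraction
  het_hap <- sample(1:2, n_all, replace = TRUE)
  ei <- 0L
  for (i in seq_len(nrow(events))) {
    ei <- ei + 1L
    e <- events[i, ]
    pos <- take(e$contig)
    gt <- if (is_het[ei]) "0/1" else "1/1"
    haps <- if (is_het[ei]) het_hap[ei] else c(1L, 2L)
    end <- if (e$svtype == "INS") pos else pos + e$len
    truth[[length(truth) + 1L]] <- data.frame(
      svtype = e$svtype, contig = e$contig, pos = pos, end = end,
      len = e$len, genotype = gt, mate_contig = NA_character_,
      mate_pos = NA_integer_, stringsAsFactors = FALSE)
    for (h in haps) {
      add_sv(list(svtype = e$svtype, contig = e$contig, hap = h, pos = pos,
                  len = e$len, src_contig = NA, src_pos = NA))
    }
  }
  if (!is.null(tra)) {
    for (i in seq_len(nrow(tra))) {
      ei <- ei + 1L
      t <- tra[i, ]
      pos <- take(t$contig)
      src_pos <- take(t$src_contig)
      gt <- if (is_het[ei]) "0/1" else "1/1"
      haps <- if (is_het[ei]) het_hap[ei] else c(1L, 2L)
      truth[[length(truth) + 1L]] <- data.frame(
        svtype = "TRA", contig = t$contig, pos = pos, end = pos, len = 0L,
        genotype = gt, mate_contig = t$src_contig, mate_pos = src_pos,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        svtype = "TRA", contig = t$contig, pos = pos, end = pos, len = 0L,
        genotype = gt, mate_contig = t$src_contig,
        mate_pos = src_pos + t$len, stringsAsFactors = FALSE)
      for (h in haps) {
        add_sv(list(svtype = "TRA", contig = t$contig, hap = h, pos = pos,
                    len = t$len, src_contig = t$src_contig, src_pos = src_pos))
      }
    }
  }
  truth <- if (length(truth) > 0L) {
    do.call(rbind, truth)
  } else {
    data.frame(svtype = character(0), contig = character(0), pos = integer(0),
               end = integer(0), len = integer(0), genotype = character(0),
               mate_contig = character(0), mate_pos = integer(0),
               stringsAsFactors = FALSE)
  }

  # novel insertion sequences, one per INS truth row, shared by both haps
  novel <- list()
  blocks <- list()
  for (cg in ctgs) {
    blocks[[cg]] <- list()
    for (h in 1:2) {
      svs <- Filter(function(s) s$contig == cg && s$hap == h, svlist)
      if (length(svs) > 0L) {
        svs <- svs[order(vapply(svs, function(s) s$pos, 0))]
      }
      rows <- list(); cursor <- 0L
      push <- function(src, s, e, strand = "+", novel_key = NA_character_) {
        rows[[length(rows) + 1L]] <<- data.frame(
          src = src, src_contig = if (src == "ref") s_ctg else NA_character_,
          src_start = s, src_end = e, strand = strand,
          novel_key = novel_key, stringsAsFactors = FALSE)
      }
      s_ctg <- cg
      for (sv in svs) {
        if (sv$pos > cursor) {
          s_ctg <- cg; push("ref", cursor, sv$pos)
        }
        if (sv$svtype == "DEL") {
          cursor <- sv$pos + sv$len
        } else if (sv$svtype == "INS") {
          key <- paste0("ins_", cg, "_", sv$pos)
          if (is.null(novel[[key]])) novel[[key]] <- random_dna(sv$len)
          push("novel", 0L, sv$len, novel_key = key)
          cursor <- sv$pos
        } else if (sv$svtype == "DUP") {
          s_ctg <- cg; push("ref", sv$pos, sv$pos + sv$len)   # first copy
          s_ctg <- cg; push("ref", sv$pos, sv$pos + sv$len)   # tandem copy
          cursor <- sv$pos + sv$len
        } else if (sv$svtype == "INV") {
          s_ctg <- cg; push("ref", sv$pos, sv$pos + sv$len, strand = "-")
          cursor <- sv$pos + sv$len
        } else if (sv$svtype == "TRA") {
          s_ctg <- sv$src_contig
          push("ref", sv$src_pos, sv$src_pos + sv$len)
          s_ctg <- cg
          cursor <- sv$pos
        }
      }
      if (cursor < nchar(ref[[cg]])) {
        s_ctg <- cg; push("ref", cursor, nchar(ref[[cg]]))
      }
      blocks[[cg]][[h]] <- do.call(rbind, rows)
    }
  }
  structure(list(ref = ref, truth = truth, blocks = blocks, novel = novel),
            class = "sv_donor")
}

donor_sequence <- function(donor, cg, hap) {
  b <- donor$blocks[[cg]][[hap]]
  pieces <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (b$src[i] == "novel") {
      pieces[i] <- donor$novel[[b$novel_key[i]]]
    } else {
      s <- substr(donor$ref[[b$src_contig[i]]], b$src_start[i] + 1L, b$src_end[i])
      pieces[i] <- if (b$strand[i] == "-") revcomp_chr(s) else s
    }
  }
  paste(pieces, collapse = "")
}

# Walk the donor blocks across read interval [a, b) and return the pieces
# (oriented reference spans / novel spans) with read offsets relative to a.
read_pieces <- function(blocks, dstart, a, b) {
  dend <- dstart + (blocks$src_end - blocks$src_start)
  first <- findInterval(a, dstart)
  out <- list()
  i <- first
  while (i <= nrow(blocks) && dstart[i] < b) {
    lo <- max(a, dstart[i]); hi <- min(b, dend[i])
    if (hi > lo) {
      off_lo <- lo - dstart[i]; off_hi <- hi - dstart[i]
      if (blocks$src[i] == "novel") {
        out[[length(out) + 1L]] <- list(type = "novel", contig = NA, ss = NA,
                                        se = NA, strand = "*",
                                        qs = lo - a, qe = hi - a)
      } else if (blocks$strand[i] == "+") {
        out[[length(out) + 1L]] <- list(type = "ref",
                                        contig = blocks$src_contig[i],
                                        ss = blocks$src_start[i] + off_lo,
                                        se = blocks$src_start[i] + off_hi,
                                        strand = "+", qs = lo - a, qe = hi - a)
      } else {
        out[[length(out) + 1L]] <- list(type = "ref",
                                        contig = blocks$src_contig[i],
                                        ss = blocks$src_end[i] - off_hi,
                                        se = blocks$src_end[i] - off_lo,
                                        strand = "-", qs = lo - a, qe = hi - a)
      }
    }
    i <- i + 1L
  }
  out
}

flip_pieces <- function(pieces, read_len) {
  out <- lapply(rev(pieces), function(p) {
    qs <- read_len - p$qe; qe <- read_len - p$qs
    p$qs <- qs; p$qe <- qe
    if (p$type == "ref") p$strand <- if (p$strand == "+") "-" else "+"
    p
  })
  out
}

# Group pieces into alignment segments: consecutive colinear reference
# pieces (same contig and strand, reference order consistent with read
# order) stay in one segment, novel pieces between them become insertions;
# anything else starts a new segment.
segment_pieces <- function(pieces) {
  segs <- list(); cur <- NULL; pending_novel <- list()
  flush <- function() {
    if (!is.null(cur) && length(cur) > 0L) segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (p in pieces) {
    if (p$type == "novel") {
      if (!is.null(cur)) pending_novel[[length(pending_novel) + 1L]] <- p
      next
    }
    if (is.null(cur)) {
      cur <- list(p); pending_novel <- list()
      next
    }
    last <- cur[[length(cur)]]
    colinear <- last$contig == p$contig && last$strand == p$strand &&
      (if (p$strand == "+") p$ss >= last$se else p$se <= last$ss)
    if (colinear) {
      cur <- c(cur, pending_novel, list(p))
    } else {
      flush()
      cur <- list(p)
    }
    pending_novel <- list()
  }
  flush()
  segs
}

cigar_str <- function(lens, ops) {
  keep <- lens > 0L
  paste0(lens[keep], ops[keep], collapse = "")
}

# Build one SAM record skeleton from a segment (list of pieces in read
# order; first and last are reference pieces).
segment_record <- function(seg, read_len) {
  refp <- Filter(function(p) p$type == "ref", seg)
  strand <- refp[[1L]]$strand
  qs <- refp[[1L]]$qs; qe <- refp[[length(refp)]]$qe
  walk <- if (strand == "+") seg else rev(seg)
  lens <- integer(0); ops <- character(0); nm_indel <- 0L
  prev <- NULL
  for (p in walk) {
    if (p$type == "novel") {
      lens <- c(lens, p$qe - p$qs); ops <- c(ops, "I")
      nm_indel <- nm_indel + (p$qe - p$qs)
      next
    }
    if (!is.null(prev)) {
      gap <- if (strand == "+") p$ss - prev$se else p$ss - prev$se
      if (gap > 0L) {
        lens <- c(lens, gap); ops <- c(ops, "D")
        nm_indel <- nm_indel + gap
      }
    }
    lens <- c(lens, p$se - p$ss); ops <- c(ops, "M")
    prev <- p
  }
  lead <- if (strand == "+") qs else read_len - qe
  trail <- if (strand == "+") read_len - qe else qs
  cigar <- cigar_str(c(lead, lens, trail), c("S", ops, "S"))
  list(contig = refp[[1L]]$contig,
       pos = min(vapply(refp, function(p) p$ss, 0)),
       strand = strand, cigar = cigar, qs = qs, qe = qe,
       nm_indel = nm_indel,
       ref_intervals = lapply(refp, function(p) c(p$qs, p$qe)))
}

#' Simulate aligned long reads from donor haplotypes
#'
#' Reads are sampled uniformly from each haplotype at half the configured
#' coverage, assigned a random sequencing orientation, and converted to
#' alignment records analytically: a read crossing a deletion gets a D
#' operation, an insertion an I operation, and duplication / inversion /
#' translocation junctions become split alignments with SA tags and correct
#' strands. Substitution errors are injected at the configured rate and
#' counted in NM.
#'
#' @param donor An `sv_donor` from [implant_svs()]. The caller seeds the RNG.
#' @param config An [sim_config()].
#' @param out_prefix Path prefix for the BAM (`<prefix>.bam` + index).
#' @return List with `bam` path and `n_reads`.
#' @export
simulate_alignments <- function(donor, config, out_prefix) {
  ctgs <- names(donor$ref)
  comp_tab <- rep(as.raw(78L), 256L)  # default 'N'
  comp_tab[as.integer(charToRaw("ACGT")) + 1L] <- charToRaw("TGCA")
  base_raw <- charToRaw("ACGT")
  lines <- character(0)
  n_reads_total <- 0L
  con_lines <- list()
  for (cg in ctgs) {
    for (h in 1:2) {
      b <- donor$blocks[[cg]][[h]]
      widths <- b$src_end - b$src_start
      dstart <- cumsum(c(0L, widths))[seq_len(nrow(b))]
      dlen <- sum(widths)
      dseq <- donor_sequence(donor, cg, h)
      n_reads <- max(1L, round(config$coverage / 2 * dlen /
                                 config$read_length_mean))
      starts <- floor(stats::runif(n_reads, 0,
                                   max(1, dlen - config$min_read_length)))
      rls <- pmax(config$min_read_length,
                  round(stats::rnorm(n_reads, config$read_length_mean,
                                     config$read_length_sd)))
      rls <- pmin(rls, dlen - starts)
      rev_read <- stats::runif(n_reads) < 0.5
      n_sub <- stats::rbinom(n_reads, rls, config$error_rate)
      recs <- vector("list", n_reads)
      for (ri in seq_len(n_reads)) {
        a <- starts[ri]; L <- rls[ri]
        pieces <- read_pieces(b, dstart, a, a + L)
        if (rev_read[ri]) pieces <- flip_pieces(pieces, L)
        segs <- segment_pieces(pieces)
        if (length(segs) == 0L) next
        seq_raw <- charToRaw(substr(dseq, a + 1L, a + L))
        if (rev_read[ri]) seq_raw <- comp_tab[as.integer(rev(seq_raw)) + 1L]
        sub_idx <- integer(0)
        if (n_sub[ri] > 0L) {
          sub_idx <- sample.int(L, n_sub[ri])
          cur <- match(seq_raw[sub_idx], base_raw)
          shift <- sample.int(3L, n_sub[ri], replace = TRUE)
          seq_raw[sub_idx] <- base_raw[((cur - 1L + shift) %% 4L) + 1L]
          sub_idx <- sort(sub_idx) - 1L   # 0-based read coords
        }
        srecs <- lapply(segs, segment_record, read_len = L)
        alens <- vapply(srecs, function(s) s$qe - s$qs, 0)
        prim <- which.max(alens)
        qname <- sprintf("r_%s_h%d_%06d", cg, h, ri)
        nms <- vapply(srecs, function(s) {
          in_ref <- sum(vapply(s$ref_intervals, function(iv) {
            sum(sub_idx >= iv[1L] & sub_idx < iv[2L])
          }, 0))
          as.integer(in_ref + s$nm_indel)
        }, 0L)
        sa_str <- vapply(seq_along(srecs), function(k) {
          others <- setdiff(seq_along(srecs), k)
          if (length(others) == 0L) return("")
          paste0(vapply(others, function(o) {
            s <- srecs[[o]]
            sprintf("%s,%d,%s,%s,60,%d;", s$contig, s$pos + 1L, s$strand,
                    s$cigar, nms[o])
          }, ""), collapse = "")
        }, "")
        out <- character(length(srecs))
        for (k in seq_along(srecs)) {
          s <- srecs[[k]]
          flag <- 0L
          if (s$strand == "-") flag <- flag + 16L
          if (k != prim) flag <- flag + 2048L
          seq_out <- if (s$strand == "-") {
            rawToChar(comp_tab[as.integer(rev(seq_raw)) + 1L])
          } else rawToChar(seq_raw)
          tags <- sprintf("NM:i:%d", nms[k])
          if (nzchar(sa_str[k])) tags <- paste0(tags, "\tSA:Z:", sa_str[k])
          out[k] <- paste(qname, flag, s$contig, s$pos + 1L, 60L, s$cigar,
                          "*", 0L, 0L, seq_out, "*", tags, sep = "\t")
        }
        recs[[ri]] <- out
        n_reads_total <- n_reads_total + 1L
      }
      con_lines[[paste(cg, h)]] <- unlist(recs, use.names = FALSE)
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", ctgs, "\tLN:", nchar(donor$ref[ctgs])))
  sam_path <- paste0(out_prefix, ".sam")
  writeLines(c(hdr, unlist(con_lines, use.names = FALSE)), sam_path)
  bam0 <- Rsamtools::asBam(sam_path, paste0(out_prefix, ".unsorted"),
                           indexDestination = FALSE, overwrite = TRUE)
  sorted <- Rsamtools::sortBam(bam0, out_prefix)
  Rsamtools::indexBam(sorted)
  unlink(c(sam_path, bam0))
  list(bam = sorted, n_reads = n_reads_total)
}

#' Run the full simulator
#'
#' Generates a reference, implants variants, writes the reference FASTA, a
#' sorted indexed BAM of simulated alignments and a truth VCF.
#'
#' @param config An [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `ref_fasta`, `bam`, `truth_vcf`, `truth` (data.frame),
#'   `donor` and `config`.
#' @export
sv_simulate <- function(config = sim_config(), dir = tempfile("svsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  refset <- simulate_reference(config$ref_length, seed = config$seed,
                               n_contigs = config$n_contigs)
  set.seed(config$seed + 1L)
  donor <- implant_svs(refset, config)
  ref_fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(refset, ref_fasta)
  set.seed(config$seed + 2L)
  aln <- simulate_alignments(donor, config, file.path(dir, "reads"))
  truth_vcf <- file.path(dir, "truth.vcf")
  write_truth_vcf(donor$truth, refset, truth_vcf)
  list(ref_fasta = ref_fasta, bam = aln$bam, truth_vcf = truth_vcf,
       truth = donor$truth, donor = donor, config = config,
       n_reads = aln$n_reads)
}

write_truth_vcf <- function(truth, refset, path) {
  contigs <- data.frame(name = names(refset),
                        length = Biostrings::width(refset))
  calls <- truth
  n <- nrow(calls)
  calls$svlen <- calls$len
  calls$support <- rep(0L, n)
  calls$min_support <- rep(0L, n)
  calls$filter <- rep("PASS", n)
  write_vcf(calls, contigs, path, reference = refset, sample = "TRUTH")
}

#' Label window submatrices against a truth set
#'
#' A submatrix is labelled 1 iff it overlaps any truth SV interval
#' (insertions and translocation junctions count as 1 bp intervals at their
#' anchors; translocation mate coordinates label the mate contig).
#'
#' @param truth Truth data.frame (as in `sv_donor$truth` or from
#'   [read_truth_vcf()]).
#' @param ws An `sv_window_set`.
#' @return Integer 0/1 matrix of windows x 10 submatrices.
#' @export
label_windows <- function(truth, ws) {
  n <- nrow(ws$windows)
  labels <- matrix(0L, n, SUBS_PER_WINDOW)
  iv <- truth_intervals(truth)
  iv <- iv[iv$contig == ws$contig, , drop = FALSE]
  if (nrow(iv) == 0L || n == 0L) return(labels)
  sub_start <- as.vector(t(outer(ws$windows$start,
                                 (seq_len(SUBS_PER_WINDOW) - 1L) * SUB_LEN, "+")))
  subs <- IRanges::IRanges(start = sub_start + 1L, width = SUB_LEN)
  tr <- IRanges::IRanges(start = iv$start + 1L,
                         end = pmax(iv$end, iv$start + 1L))
  hits <- IRanges::overlapsAny(subs, tr)
  labels[matrix(hits, n, SUBS_PER_WINDOW, byrow = TRUE)] <- 1L
  labels
}

# Orient two-ended (TRA/BND) records so the lexicographically smaller
# (contig, pos) end comes first, making both call and truth comparable.
normalize_tra_ends <- function(df) {
  if (is.null(df$mate_contig) || nrow(df) == 0L) return(df)
  two <- df$svtype %in% c("TRA", "BND") & !is.na(df$mate_contig)
  flip <- two & (df$mate_contig < df$contig |
                   (df$mate_contig == df$contig & df$mate_pos < df$pos))
  if (any(flip)) {
    tmp_c <- df$contig[flip]; tmp_p <- df$pos[flip]
    df$contig[flip] <- df$mate_contig[flip]
    df$pos[flip] <- df$mate_pos[flip]
    df$mate_contig[flip] <- tmp_c
    df$mate_pos[flip] <- tmp_p
    df$end[flip] <- df$pos[flip]
  }
  df
}

truth_intervals <- function(truth) {
  if (nrow(truth) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  main <- data.frame(contig = truth$contig, start = truth$pos,
                     end = ifelse(truth$svtype %in% c("INS", "TRA"),
                                  truth$pos + 1L, truth$end),
                     stringsAsFactors = FALSE)
  mates <- truth[!is.na(truth$mate_contig), , drop = FALSE]
  if (nrow(mates) > 0L) {
    main <- rbind(main, data.frame(contig = mates$mate_contig,
                                   start = mates$mate_pos,
                                   end = mates$mate_pos + 1L,
                                   stringsAsFactors = FALSE))
  }
  main
}

#' Compare calls against a truth set
#'
#' A call matches a truth entry iff the SV types agree, the breakpoints are
#' within `pos_tolerance` (inclusive) on the same contig, and the shorter
#' length is at least `len_ratio` of the longer (skipped for TRA/BND, which
#' instead require the mate ends to match within tolerance). Matching is
#' greedy one-to-one by breakpoint distance.
#'
#' @param calls data.frame of calls (e.g. PASS rows of `sv_calls`, or a
#'   parsed VCF).
#' @param truth Truth data.frame.
#' @param pos_tolerance Breakpoint tolerance (bp).
#' @param len_ratio Minimum length ratio in (0, 1].
#' @return List with `per_type` (data.frame of n_truth, n_calls, tp,
#'   precision, recall, f1 per type), `overall` (micro-averaged), and
#'   `offsets` (named list of absolute breakpoint offsets of matches).
#' @export
evaluate_calls <- function(calls, truth, pos_tolerance = 500L,
                           len_ratio = 0.7) {
  if (is.null(calls$len) && !is.null(calls$svlen)) calls$len <- calls$svlen
  if (is.null(truth$len) && !is.null(truth$svlen)) truth$len <- truth$svlen
  calls <- normalize_tra_ends(calls)
  truth <- normalize_tra_ends(truth)
  types <- sort(unique(c(calls$svtype, truth$svtype)))
  per <- list(); offsets <- list()
  tp_all <- 0L
  for (tp in types) {
    cs <- calls[calls$svtype == tp, , drop = FALSE]
    ts <- truth[truth$svtype == tp, , drop = FALSE]
    matched_t <- rep(FALSE, nrow(ts))
    offs <- numeric(0)
    tpn <- 0L
    if (nrow(cs) > 0L) cs <- cs[order(cs$contig, cs$pos), , drop = FALSE]
    for (i in seq_len(nrow(cs))) {
      cand <- which(!matched_t & ts$contig == cs$contig[i] &
                      abs(ts$pos - cs$pos[i]) <= pos_tolerance)
      if (tp %in% c("TRA", "BND")) {
        if (!is.null(cs$mate_contig) && length(cand) > 0L) {
          ok <- !is.na(cs$mate_contig[i]) &
            ts$mate_contig[cand] == cs$mate_contig[i] &
            abs(ts$mate_pos[cand] - cs$mate_pos[i]) <= pos_tolerance
          cand <- cand[which(ok)]
        }
      } else if (length(cand) > 0L) {
        lens <- ts$len[cand]
        rr <- pmin(lens, cs$len[i]) / pmax(lens, cs$len[i])
        cand <- cand[rr >= len_ratio]
      }
      if (length(cand) == 0L) next
      j <- cand[which.min(abs(ts$pos[cand] - cs$pos[i]))]
      matched_t[j] <- TRUE
      tpn <- tpn + 1L
      offs <- c(offs, abs(ts$pos[j] - cs$pos[i]))
    }
    prec <- if (nrow(cs) > 0L) tpn / nrow(cs) else 0
    rec <- if (nrow(ts) > 0L) tpn / nrow(ts) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[[tp]] <- data.frame(svtype = tp, n_truth = nrow(ts),
                            n_calls = nrow(cs), tp = tpn, precision = prec,
                            recall = rec, f1 = f1, stringsAsFactors = FALSE)
    offsets[[tp]] <- offs
    tp_all <- tp_all + tpn
  }
  per_type <- do.call(rbind, per)
  rownames(per_type) <- NULL
  prec_all <- if (nrow(calls) > 0L) tp_all / nrow(calls) else 0
  rec_all <- if (nrow(truth) > 0L) tp_all / nrow(truth) else 0
  f1_all <- if (prec_all + rec_all > 0) {
    2 * prec_all * rec_all / (prec_all + rec_all)
  } else 0
  list(per_type = per_type,
       overall = list(tp = tp_all, n_calls = nrow(calls),
                      n_truth = nrow(truth), precision = prec_all,
                      recall = rec_all, f1 = f1_all),
       offsets = offsets)
}
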