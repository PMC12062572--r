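# VCF 4.2 emission and truth-set parsing. Calls are written with symbolic
# ALT alleles (<DEL>, <INS>, <DUP>, <INV>); translocations become two mated
# BND records in bracket notation. Internal coordinates are 0-based
# half-open and converted to 1-based only here.

VCF_VERSION_LINE <- "##fileformat=VCFv4.2"

vcf_header <- function(contigs, sample) {
  c(VCF_VERSION_LINE,
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    paste0("##source=svscout-", as.character(utils::packageVersion("svscout"))),
    paste0("##contig=<ID=", contigs$name, ",length=", contigs$length, ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
    "##INFO=<ID=MINSUPPORT,Number=1,Type=Integer,Description=\"Dynamic minimum support threshold at this locus\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate contig of a breakend\">",
    "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"Mate position of a breakend\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of the mate breakend\">",
    "##FILTER=<ID=LowSupport,Description=\"Supporting reads below the dynamic minimum\">",
    "##FILTER=<ID=MinLength,Description=\"Variant shorter than the minimum SV length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

ref_base_at <- function(reference, contig, pos1) {
  if (is.null(reference)) return("N")
  seqs <- reference
  if (!contig %in% names(seqs)) return("N")
  if (pos1 < 1L || pos1 > Biostrings::width(seqs[contig])) return("N")
  as.character(Biostrings::subseq(seqs[[contig]], pos1, pos1))
}

#' Write calls to a VCF 4.2 file
#'
#' @param calls An `sv_calls` data.frame from [call_variants()] (or any
#'   data.frame with the same columns).
#' @param contigs data.frame with columns `name` and `length` covering every
#'   call contig.
#' @param path Output path.
#' @param reference Optional `DNAStringSet` supplying REF bases ("N" when
#'   absent).
#' @param sample Sample name for the single genotype column.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, contigs, path, reference = NULL,
                      sample = "SAMPLE") {
  stopifnot(all(c("name", "length") %in% names(contigs)))
  bad <- setdiff(unique(c(calls$contig,
                          calls$mate_contig[!is.na(calls$mate_contig)])),
                 contigs$name)
  if (length(bad) > 0L) {
    stop("call on contig absent from metadata: ", paste(bad, collapse = ", "))
  }
  recs <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    gt <- if (is.na(cl$genotype)) "./." else cl$genotype
    if (cl$svtype == "TRA") {
      id1 <- sprintf("svscout.BND.%d.1", i)
      id2 <- sprintf("svscout.BND.%d.2", i)
      p1 <- cl$pos + 1L
      p2 <- cl$mate_pos + 1L
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;CHR2=%s;END2=%d;SUPPORT=%d;MINSUPPORT=%d",
                       id2, cl$mate_contig, p2, cl$support, cl$min_support)
      info2 <- sprintf("SVTYPE=BND;MATEID=%s;CHR2=%s;END2=%d;SUPPORT=%d;MINSUPPORT=%d",
                       id1, cl$contig, p1, cl$support, cl$min_support)
      rb1 <- ref_base_at(reference, cl$contig, p1)
      rb2 <- ref_base_at(reference, cl$mate_contig, p2)
      recs[[length(recs) + 1L]] <- data.frame(
        contig = cl$contig, pos1 = p1,
        line = paste(cl$contig, p1, id1, rb1,
                     sprintf("%s[%s:%d[", rb1, cl$mate_contig, p2),
                     ".", cl$filter, info1, "GT", gt, sep = "\t"),
        stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- data.frame(
        contig = cl$mate_contig, pos1 = p2,
        line = paste(cl$mate_contig, p2, id2, rb2,
                     sprintf("%s]%s:%d]", rb2, cl$contig, p1),
                     ".", cl$filter, info2, "GT", gt, sep = "\t"),
        stringsAsFactors = FALSE)
    } else {
      pos1 <- cl$pos + 1L
      end1 <- if (cl$svtype == "INS") pos1 else pos1 + cl$svlen
      svlen <- if (cl$svtype == "DEL") -cl$svlen else cl$svlen
      id <- sprintf("svscout.%s.%d", cl$svtype, i)
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d;MINSUPPORT=%d",
                      cl$svtype, end1, svlen, cl$support, cl$min_support)
      rb <- ref_base_at(reference, cl$contig, pos1)
      recs[[length(recs) + 1L]] <- data.frame(
        contig = cl$contig, pos1 = pos1,
        line = paste(cl$contig, pos1, id, rb, sprintf("<%s>", cl$svtype),
                     ".", cl$filter, info, "GT", gt, sep = "\t"),
        stringsAsFactors = FALSE)
    }
  }
  hdr <- vcf_header(contigs, sample)
  if (length(recs) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  recs <- do.call(rbind, recs)
  recs$contig <- factor(recs$contig, levels = contigs$name)
  recs <- recs[order(recs$contig, recs$pos1), , drop = FALSE]
  writeLines(c(hdr, recs$line), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
}

#' Read a (truth) VCF into a structural-variant table
#'
#' Accepts symbolic and sequence-resolved alleles; SVTYPE/SVLEN/END are taken
#' from INFO when present and otherwise inferred from the allele lengths.
#' Records that cannot be typed are skipped with a warning. BND mate pairs
#' are collapsed to one TRA entry per junction.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return data.frame with columns svtype, contig, pos (0-based), end, len,
#'   genotype, mate_contig, mate_pos.
#' @export
read_truth_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  empty <- data.frame(svtype = character(0), contig = character(0),
                      pos = integer(0), end = integer(0), len = integer(0),
                      genotype = character(0), mate_contig = character(0),
                      mate_pos = integer(0), filter = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(fix) == 0L) return(empty)
  contig <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  info <- fix[, "INFO"]
  filt <- fix[, "FILTER"]
  gtmat <- vcf@gt
  gt <- if (!is.null(gtmat) && ncol(gtmat) >= 2L) {
    sub(":.*", "", gtmat[, 2L])
  } else {
    rep(NA_character_, nrow(fix))
  }
  svtype <- info_field(info, "SVTYPE")
  sym <- regmatches(alt, regexec("^<([A-Z]+)>$", alt))
  sym <- vapply(sym, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
  svtype[is.na(svtype)] <- sym[is.na(svtype)]
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  endf <- suppressWarnings(as.integer(info_field(info, "END")))
  seq_ok <- grepl("^[ACGTNacgtn]+$", ref) & grepl("^[ACGTNacgtn]+$", alt)
  infer <- is.na(svtype) & seq_ok
  d <- nchar(alt) - nchar(ref)
  svtype[infer & d >= 1] <- "INS"
  svtype[infer & d <= -1] <- "DEL"
  svlen[is.na(svlen) & seq_ok] <- d[is.na(svlen) & seq_ok]
  drop <- is.na(svtype)
  if (any(drop)) {
    warning(sum(drop), " VCF record(s) without a resolvable SV type skipped")
  }
  rows <- list()
  bnd_seen <- character(0)
  for (i in which(!drop)) {
    tp <- svtype[i]
    p0 <- pos1[i] - 1L
    if (tp %in% c("BND", "TRA")) {
      mc <- info_field(info[i], "CHR2")
      mp <- suppressWarnings(as.integer(info_field(info[i], "END2")))
      if (is.na(mc)) {
        bm <- regmatches(alt[i], regexec("[][]([^:]+):([0-9]+)[][]", alt[i]))[[1]]
        if (length(bm) >= 3L) { mc <- bm[2L]; mp <- as.integer(bm[3L]) }
      }
      if (is.na(mc)) next
      mp0 <- mp - 1L
      a <- paste(contig[i], p0, sep = ":"); b <- paste(mc, mp0, sep = ":")
      pairkey <- paste(sort(c(a, b)), collapse = "|")
      if (pairkey %in% bnd_seen) next
      bnd_seen <- c(bnd_seen, pairkey)
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = "TRA", contig = contig[i], pos = p0, end = p0, len = 0L,
        genotype = gt[i], mate_contig = mc, mate_pos = mp0,
        filter = filt[i], stringsAsFactors = FALSE)
    } else {
      len <- abs(svlen[i])
      # with POS the first affected base, END - POS spans the event length
      if (is.na(len) && !is.na(endf[i])) len <- endf[i] - pos1[i]
      if (is.na(len)) next
      end0 <- if (tp == "INS") p0 else p0 + len
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = tp, contig = contig[i], pos = p0, end = end0, len = len,
        genotype = gt[i], mate_contig = NA_character_,
        mate_pos = NA_integer_, filter = filt[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
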