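# Per-site feature extraction and window tiling.

FWD_DEL <- 2L; REV_OFF <- 10L

test_that("region with no reads yields an all-zero matrix of the right shape", {
  bam <- hand_bam(list(list(qname = "r1", flag = 0L, contig = "ctgA",
                            pos1 = 50001L, cigar = "100M")))
  fm <- extract_site_features(bam, list(contig = "ctgA", start = 0L,
                                        end = 2000L))
  expect_equal(dim(fm$counts), c(2000L, 20L))
  expect_true(all(fm$counts == 0L))
})

test_that("a CIGAR deletion increments the deletion channel on the correct strand", {
  # forward read 50M100D50M starting at 0-based 1000
  recs <- list(list(qname = "r1", flag = 0L, contig = "ctgA", pos1 = 1001L,
                    cigar = "50M100D50M"))
  bam <- hand_bam(recs)
  fm <- extract_site_features(bam, list(contig = "ctgA", start = 1000L,
                                        end = 1200L), min_op = 30L)
  del_fwd <- fm$counts[, FWD_DEL]
  expect_equal(sum(del_fwd), 100L)
  expect_true(all(del_fwd[51:150] == 1L))       # deleted span rows 51..150
  expect_true(all(fm$counts[, FWD_DEL + REV_OFF] == 0L))
  expect_equal(sum(fm$counts[, 1L]), 200L)      # M+D depth on forward block

  # same read flagged reverse-strand: identical counts on the reverse block
  recs[[1]]$flag <- 16L
  fm2 <- extract_site_features(hand_bam(recs),
                               list(contig = "ctgA", start = 1000L,
                                    end = 1200L), min_op = 30L)
  expect_equal(fm2$counts[, FWD_DEL + REV_OFF], del_fwd)
  expect_true(all(fm2$counts[, FWD_DEL] == 0L))
})

test_that("channel sums agree with an independent brute-force CIGAR re-parse", {
  sim <- tiny_sim()
  fm <- extract_site_features(sim$bam, list(contig = "ctg1", start = 0L,
                                            end = 120000L), min_op = 30L)
  # independent oracle: walk each primary record's CIGAR in plain R
  aln <- Rsamtools::scanBam(sim$bam,
    param = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges("ctg1", IRanges::IRanges(1, 120000)),
      what = c("pos", "cigar", "strand", "flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      mapqFilter = 20L))[[1]]
  del_fwd <- 0L; ins_rev <- 0L
  for (i in seq_along(aln$pos)) {
    ops <- regmatches(aln$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", aln$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typ <- sub("[0-9]+", "", ops)
    refpos <- aln$pos[i] - 1L
    for (k in seq_along(typ)) {
      if (typ[k] == "D" && lens[k] >= 30L) {
        span <- seq(refpos, refpos + lens[k] - 1L)
        del_fwd <- del_fwd +
          if (aln$strand[i] == "+") sum(span >= 0 & span < 120000) else 0L
      }
      if (typ[k] == "I" && lens[k] >= 30L && aln$strand[i] == "-" &&
          refpos < 120000) {
        ins_rev <- ins_rev + 1L
      }
      if (typ[k] %in% c("M", "D", "N", "=", "X")) refpos <- refpos + lens[k]
    }
  }
  expect_equal(sum(fm$counts[, FWD_DEL]), del_fwd)
  expect_equal(sum(fm$counts[, 3L + REV_OFF]), ins_rev)
})

test_that("duplicating every read exactly doubles every count", {
  recs <- list(
    list(qname = "a", flag = 0L, contig = "ctgA", pos1 = 501L,
         cigar = "30S100M50D100M40I60M"),
    list(qname = "b", flag = 16L, contig = "ctgA", pos1 = 901L,
         cigar = "120M35D80M25S"))
  fm1 <- extract_site_features(hand_bam(recs),
                               list(contig = "ctgA", start = 0L, end = 2000L))
  dup <- c(recs, lapply(recs, function(r) { r$qname <- paste0(r$qname, "2"); r }))
  fm2 <- extract_site_features(hand_bam(dup),
                               list(contig = "ctgA", start = 0L, end = 2000L))
  expect_equal(fm2$counts, 2L * fm1$counts)
})

test_that("record order does not change the extracted features", {
  recs <- list(
    list(qname = "a", flag = 0L, contig = "ctgA", pos1 = 501L, cigar = "200M"),
    list(qname = "b", flag = 0L, contig = "ctgA", pos1 = 401L,
         cigar = "100M60D100M"),
    list(qname = "c", flag = 16L, contig = "ctgA", pos1 = 601L,
         cigar = "50S150M"))
  fm1 <- extract_site_features(hand_bam(recs),
                               list(contig = "ctgA", start = 0L, end = 1500L))
  fm2 <- extract_site_features(hand_bam(rev(recs)),
                               list(contig = "ctgA", start = 0L, end = 1500L))
  expect_equal(fm1$counts, fm2$counts)
})

test_that("unknown contig and malformed regions are rejected", {
  sim <- tiny_sim()
  expect_error(extract_site_features(sim$bam,
                                     list(contig = "chrZ", start = 0L,
                                          end = 100L)),
               "contig not found")
  expect_error(extract_site_features(sim$bam,
                                     list(contig = "ctg1", start = 10L,
                                          end = 5L)),
               "bounds")
})

test_that("window tiling covers every position once with padding flagged", {
  mk_fm <- function(span) {
    structure(list(contig = "c", start = 0L, end = span,
                   counts = matrix(seq_len(span * 20L) %% 7L, span, 20L)),
              class = "sv_feature_matrix")
  }
  ws <- tile_windows(mk_fm(4000L))
  expect_equal(nrow(ws$windows), 2L)
  b2 <- get_window_batch(ws, 2L)
  expect_false(any(b2$pad_mask))
  expect_equal(b2$x, matrix(as.numeric(mk_fm(4000L)$counts[2001:4000, ]),
                            2000L, 20L))

  ws <- tile_windows(mk_fm(2100L))
  expect_equal(nrow(ws$windows), 2L)
  b2 <- get_window_batch(ws, 2L)
  expect_equal(b2$pad_mask, c(FALSE, rep(TRUE, 9L)))   # 1 part-filled, 9 padded
  expect_true(all(b2$x[101:2000, ] == 0))
  expect_true(all(b2$x[1:100, ] == mk_fm(2100L)$counts[2001:2100, ]))

  ws0 <- tile_windows(mk_fm(0L))
  expect_equal(nrow(ws0$windows), 0L)
})
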