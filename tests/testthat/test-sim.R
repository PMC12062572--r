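# The alignment simulator: determinism, sequence composition, donor
# bookkeeping, CIGAR self-consistency, coverage and evaluation matching.

test_that("reference simulation is deterministic per seed with uniform composition", {
  r1 <- simulate_reference(20000L, seed = 5L, n_contigs = 2L)
  r2 <- simulate_reference(20000L, seed = 5L, n_contigs = 2L)
  expect_identical(as.character(r1), as.character(r2))
  r3 <- simulate_reference(20000L, seed = 6L, n_contigs = 2L)
  mism <- mean(strsplit(as.character(r1[[1]]), "")[[1]] !=
                 strsplit(as.character(r3[[1]]), "")[[1]])
  expect_gt(mism, 0.2)   # expected ~0.75 for independent uniform sequences
  gc <- Biostrings::letterFrequency(simulate_reference(100000L, seed = 7L)[[1]],
                                    "GC", as.prob = TRUE)
  expect_gt(gc, 0.45); expect_lt(gc, 0.55)
  expect_error(simulate_reference(500L), ">= 10000")
})

test_that("implanted variants change donor length by the expected amount", {
  ref <- simulate_reference(40000L, seed = 3L)
  base <- sim_config(ref_length = 40000L, n_contigs = 1L, het_fraction = 0,
                     n_sv = c(DEL = 1L, INS = 0L, DUP = 0L, INV = 0L, TRA = 0L),
                     sv_size = c(500L, 500L), seed = 3L)
  set.seed(3)
  donor <- implant_svs(ref, base)
  expect_equal(nchar(svscout:::donor_sequence(donor, "ctg1", 1L)), 39500L)
  expect_equal(nchar(svscout:::donor_sequence(donor, "ctg1", 2L)), 39500L)

  base$n_sv <- c(DEL = 0L, INS = 1L, DUP = 0L, INV = 0L, TRA = 0L)
  base$sv_size <- c(300L, 300L)
  set.seed(3)
  donor <- implant_svs(ref, base)
  expect_equal(nchar(svscout:::donor_sequence(donor, "ctg1", 1L)), 40300L)

  sim <- tiny_sim()
  expect_equal(nrow(sim$truth), 3L + 3L + 3L + 3L + 2L)
  expect_true(all(sim$truth$genotype %in% c("0/1", "1/1")))
})

test_that("simulation is fully deterministic per seed", {
  cfg <- sim_config(ref_length = 80000L,
                    n_sv = c(DEL = 2L, INS = 2L, DUP = 1L, INV = 1L, TRA = 2L),
                    coverage = 8, seed = 99L)
  s1 <- sv_simulate(cfg, dir = file.path(tempdir(), "det1"))
  s2 <- sv_simulate(cfg, dir = file.path(tempdir(), "det2"))
  expect_identical(s1$truth, s2$truth)
  read_all <- function(bam) {
    ga <- GenomicAlignments::readGAlignments(bam,
      param = Rsamtools::ScanBamParam(what = c("qname", "flag", "seq")))
    paste(S4Vectors::mcols(ga)$qname, S4Vectors::mcols(ga)$flag,
          GenomicAlignments::cigar(ga), BiocGenerics::start(ga),
          as.character(S4Vectors::mcols(ga)$seq))
  }
  expect_identical(read_all(s1$bam), read_all(s2$bam))
})

test_that("every simulated record is CIGAR/SEQ consistent", {
  sim <- tiny_sim()
  ga <- GenomicAlignments::readGAlignments(sim$bam,
    param = Rsamtools::ScanBamParam(what = "seq"))
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(GenomicAlignments::cigar(ga))
  expect_equal(qw, Biostrings::width(S4Vectors::mcols(ga)$seq))
  expect_gt(length(ga), 0L)
})

test_that("mean depth is within 15% of the requested coverage", {
  sim <- tiny_sim()   # 20x requested
  fm <- extract_site_features(sim$bam, list(contig = "ctg1", start = 0L,
                                            end = 120000L), min_mapq = 0L)
  cov <- feature_coverage(fm)
  expect_gt(cov, 20 * 0.85)
  expect_lt(cov, 20 * 1.15)
})

test_that("a heterozygous variant is carried by roughly half the spanning reads", {
  cfg <- sim_config(ref_length = 60000L, n_contigs = 1L, het_fraction = 1,
                    n_sv = c(DEL = 1L, INS = 0L, DUP = 0L, INV = 0L, TRA = 0L),
                    sv_size = c(500L, 500L), coverage = 30,
                    read_length_mean = 4000L, read_length_sd = 500L,
                    seed = 33L)
  sim <- sv_simulate(cfg, dir = file.path(tempdir(), "hetsim"))
  del <- sim$truth[sim$truth$svtype == "DEL", ]
  sigs <- extract_signatures(sim$bam,
                             data.frame(contig = "ctg1",
                                        start = max(del$pos - 2000L, 0L),
                                        end = del$end + 2000L))
  carriers <- length(unique(sigs$read[sigs$svtype == "DEL"]))
  expect_gte(carriers, 8L)
  expect_lte(carriers, 22L)
})

test_that("window labels mark exactly the truth-overlapping submatrices", {
  truth <- data.frame(svtype = c("DEL", "INS"), contig = "c",
                      pos = c(2500L, 7010L), end = c(3000L, 7010L),
                      len = c(500L, 100L), genotype = "1/1",
                      mate_contig = NA_character_, mate_pos = NA_integer_)
  fm <- structure(list(contig = "c", start = 0L, end = 10000L,
                       counts = matrix(0L, 10000L, 20L)),
                  class = "sv_feature_matrix")
  ws <- tile_windows(fm)
  lab <- label_windows(truth, ws)
  expect_equal(dim(lab), c(5L, 10L))
  expect_true(all(lab[1L, ] == 0))                    # window far from SVs
  expect_equal(which(lab[2L, ] == 1L), c(3L, 4L, 5L)) # DEL spans 2500-3000
  expect_equal(which(lab[4L, ] == 1L), 6L)            # INS anchor at 7010
  expect_identical(label_windows(truth, ws), lab)     # idempotent
})

test_that("evaluation matches calls to truth within tolerance and length ratio", {
  truth <- data.frame(svtype = c("DEL", "INS"), contig = "c",
                      pos = c(1000L, 9000L), end = c(1500L, 9000L),
                      len = c(500L, 200L), genotype = "1/1",
                      mate_contig = NA_character_, mate_pos = NA_integer_)
  self <- truth
  ev <- evaluate_calls(self, truth)
  expect_equal(ev$overall$f1, 1)
  expect_true(all(ev$per_type$f1 == 1))

  none <- truth[0, ]
  ev0 <- evaluate_calls(none, truth)
  expect_equal(ev0$overall$recall, 0)
  expect_equal(ev0$overall$precision, 0)

  shifted <- truth
  shifted$pos <- shifted$pos + 500L   # exactly at tolerance: still a match
  ev1 <- evaluate_calls(shifted, truth, pos_tolerance = 500L)
  expect_equal(ev1$overall$recall, 1)
  shifted$pos <- shifted$pos + 1L
  ev2 <- evaluate_calls(shifted, truth, pos_tolerance = 500L)
  expect_equal(ev2$overall$recall, 0)

  short <- truth
  short$len <- c(300L, 200L)          # 300/500 = 0.6 < 0.7 fails length test
  ev3 <- evaluate_calls(short, truth, len_ratio = 0.7)
  expect_equal(ev3$per_type$tp[ev3$per_type$svtype == "DEL"], 0L)
  expect_equal(ev3$per_type$tp[ev3$per_type$svtype == "INS"], 1L)
})
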