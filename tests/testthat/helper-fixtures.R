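# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small diploid simulation with all five SV types.
tiny_sim <- function() {
  fixture("tiny_sim", function() {
    cfg <- sim_config(ref_length = 120000L,
                      n_sv = c(DEL = 3L, INS = 3L, DUP = 3L, INV = 3L,
                               TRA = 2L),
                      sv_size = c(60L, 800L), coverage = 20,
                      read_length_mean = 6000L, read_length_sd = 1000L,
                      tra_insert_size = c(2000L, 3000L), seed = 42L)
    sv_simulate(cfg, dir = file.path(tempdir(), "svscout_tiny_sim"))
  })
}

# Write a SAM built from hand-crafted records and return an indexed BAM.
# Records are lists with qname, flag, contig, pos1, mapq, cigar, seq, tags.
hand_bam <- function(records, contig_lengths = c(ctgA = 100000L,
                                                 ctgB = 100000L)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(contig_lengths), "\tLN:", contig_lengths))
  lines <- vapply(records, function(r) {
    seq <- r$seq %||% strrep("A", GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar))
    base <- paste(r$qname, r$flag, r$contig, r$pos1, r$mapq %||% 60L, r$cigar,
                  "*", 0L, 0L, seq, "*", sep = "\t")
    if (!is.null(r$tags)) base <- paste(base, r$tags, sep = "\t")
    base
  }, "")
  writeLines(c(hdr, lines), sam)
  pre <- tempfile()
  bam0 <- Rsamtools::asBam(sam, paste0(pre, ".unsorted"),
                           indexDestination = FALSE, overwrite = TRUE)
  sorted <- Rsamtools::sortBam(bam0, pre)
  Rsamtools::indexBam(sorted)
  unlink(c(sam, bam0))
  sorted
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for mean-shift: evaluate the Gaussian KDE on a 1-unit
# grid, hill-climb each point to its local maximum, then merge maxima closer
# than bandwidth/2 (same radius as the implementation's mode-merging rule).
grid_kde_clusters <- function(positions, bandwidth) {
  lo <- floor(min(positions) - 3 * bandwidth)
  hi <- ceiling(max(positions) + 3 * bandwidth)
  grid <- lo:hi
  dens <- vapply(grid, function(g) {
    sum(exp(-(g - positions)^2 / (2 * bandwidth^2)))
  }, 0)
  climb <- function(x0) {
    i <- which.min(abs(grid - x0))
    repeat {
      left <- if (i > 1L) dens[i - 1L] else -Inf
      right <- if (i < length(grid)) dens[i + 1L] else -Inf
      if (right > dens[i] && right >= left) i <- i + 1L
      else if (left > dens[i]) i <- i - 1L
      else return(grid[i])
    }
  }
  modes <- vapply(positions, climb, 0)
  ord <- order(modes)
  cl <- integer(length(positions))
  cid <- 1L
  anchor <- modes[ord[1L]]
  cl[ord[1L]] <- 1L
  for (k in seq_along(ord)[-1L]) {
    if (modes[ord[k]] - anchor > bandwidth / 2) {
      cid <- cid + 1L
      anchor <- modes[ord[k]]
    }
    cl[ord[k]] <- cid
  }
  cl
}

# Canonical form of a clustering for comparison: sorted member lists.
partition_sets <- function(assignment) {
  unname(lapply(split(seq_along(assignment), assignment), sort))
}
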