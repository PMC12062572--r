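# End-to-end orchestration: feature extraction -> window classification ->
# candidate regions -> signature extraction -> clustering -> support filter
# and genotyping -> VCF. Plus the training and evaluation entry points used
# by the command-line wrapper.

#' Call structural variants from a BAM file
#'
#' Runs the full pipeline per contig and merges results in deterministic
#' contig order. Candidate regions are the merged model-positive 200 bp
#' submatrices, extended by the largest clustering bandwidth before
#' signature extraction.
#'
#' @param bam Coordinate-sorted, indexed BAM path.
#' @param model A trained `sv_model` (or a checkpoint path).
#' @param output_vcf Optional VCF output path.
#' @param reference Optional reference FASTA path (REF bases in the VCF).
#' @param contigs Contig names to process (default: all in the header).
#' @param cluster_cfg A [cluster_config()].
#' @param support A [support_params()].
#' @param min_svlen Minimum PASS SV length (bp).
#' @param min_mapq,min_op Feature/signature extraction thresholds.
#' @param positive_threshold Submatrix probability threshold (default from
#'   the model configuration).
#' @param epsilon,priors Genotyping parameters, see [call_variants()].
#' @param sample Sample name for the VCF.
#' @param verbose Log progress to stderr.
#' @return List of class `sv_call_result` with `calls` (data.frame),
#'   `regions`, `coverage`, `mean_error_rate` and `report` (per-type PASS
#'   counts and stage timings).
#' @export
sv_call <- function(bam, model, output_vcf = NULL, reference = NULL,
                    contigs = NULL, cluster_cfg = cluster_config(),
                    support = support_params(), min_svlen = 50L,
                    min_mapq = 20L, min_op = 30L, positive_threshold = NULL,
                    epsilon = 0.1, priors = c(0.4, 0.4, 0.2),
                    sample = "SAMPLE", verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(model)) model <- sv_load_model(model)
  threshold <- positive_threshold %||% model$config$positive_threshold
  lens <- bam_contig_lengths(bam)
  if (is.null(contigs)) contigs <- names(lens)
  missing_ctg <- setdiff(contigs, names(lens))
  if (length(missing_ctg) > 0L) {
    stop("contig not found in alignment file: ",
         paste(missing_ctg, collapse = ", "))
  }
  timings <- c()
  ws_list <- list(); depth <- list()
  for (cg in contigs) {
    if (verbose) log_msg("features: %s", cg)
    fm <- extract_site_features(bam, list(contig = cg, start = 0L,
                                          end = unname(lens[cg])),
                                min_mapq = min_mapq, min_op = min_op)
    ws_list[[cg]] <- tile_windows(fm)
    nch <- length(FEATURE_CHANNELS)
    depth[[cg]] <- fm$counts[, 1L] + fm$counts[, nch + 1L]
  }
  timings[["features"]] <- proc.time()[["elapsed"]] - t0
  c_global <- mean(unlist(lapply(depth, mean), use.names = FALSE))
  t1 <- proc.time()[["elapsed"]]
  regions <- list()
  for (cg in contigs) {
    if (verbose) log_msg("classify: %s", cg)
    probs <- predict_window_set(ws_list[[cg]], model, c_global)
    regions[[cg]] <- candidate_regions(ws_list[[cg]], probs, threshold)
  }
  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  timings[["classify"]] <- proc.time()[["elapsed"]] - t1
  t2 <- proc.time()[["elapsed"]]
  extend <- max(cluster_cfg$bandwidth_del, cluster_cfg$bandwidth_ins,
                cluster_cfg$bandwidth_dup, cluster_cfg$bandwidth_inv,
                cluster_cfg$high_quality_bandwidth)
  search <- regions
  if (nrow(search) > 0L) {
    search$start <- pmax(search$start - extend, 0L)
    search$end <- pmin(search$end + extend, unname(lens[search$contig]))
  }
  sigs <- extract_signatures(bam, search, min_mapq = min_mapq,
                             min_sv_candidate = min_op)
  mean_err <- if (nrow(sigs) > 0L) mean(sigs$error_rate) else 0
  subclusters <- cluster_signatures(sigs, cluster_cfg)
  timings[["signatures"]] <- proc.time()[["elapsed"]] - t2
  t3 <- proc.time()[["elapsed"]]
  local_cov <- function(contig, s, e) {
    d <- depth[[contig]]
    lo <- max(s - 500L, 0L) + 1L
    hi <- min(e + 500L, length(d))
    if (hi < lo) return(0)
    mean(d[lo:hi])
  }
  ref_count <- function(contig, s, e, exclude) {
    lo <- max(s - 50L, 0L); hi <- min(e + 50L, unname(lens[contig]))
    param <- Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(contig, IRanges::IRanges(lo + 1L, max(hi, lo + 1L))),
      what = c("qname"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      mapqFilter = min_mapq)
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    span <- BiocGenerics::start(ga) <= lo + 1L & BiocGenerics::end(ga) >= hi
    qn <- S4Vectors::mcols(ga)$qname[span]
    length(setdiff(unique(qn), exclude))
  }
  calls <- call_variants(subclusters,
                         coverage = list(global = c_global, local = local_cov,
                                         ref_count = ref_count),
                         params = support, error_rate = mean_err,
                         epsilon = epsilon, priors = priors,
                         min_svlen = min_svlen)
  timings[["calling"]] <- proc.time()[["elapsed"]] - t3
  if (!is.null(output_vcf)) {
    refset <- if (!is.null(reference)) {
      rs <- Biostrings::readDNAStringSet(reference)
      names(rs) <- sub("\\s.*$", "", names(rs))
      rs
    } else NULL
    write_vcf(calls, data.frame(name = names(lens), length = unname(lens)),
              output_vcf, reference = refset, sample = sample)
  }
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  report <- list(
    n_regions = nrow(regions), n_signatures = nrow(sigs),
    n_calls = nrow(calls), n_pass = nrow(pass),
    pass_by_type = table(factor(pass$svtype,
                                levels = c("DEL", "INS", "DUP", "INV", "TRA"))),
    coverage = c_global, mean_error_rate = mean_err, timings = timings)
  if (verbose) {
    log_msg("calls: %d PASS / %d total (coverage %.1fx, error %.3f)",
            report$n_pass, report$n_calls, c_global, mean_err)
  }
  structure(list(calls = calls, regions = regions, coverage = c_global,
                 mean_error_rate = mean_err, report = report),
            class = "sv_call_result")
}

#' Train the window classifier from a BAM and a truth set
#'
#' Extracts feature matrices for the given contigs, labels 200 bp
#' submatrices by overlap with the truth intervals and trains the selected
#' model variant.
#'
#' @param bam Indexed BAM path.
#' @param truth Truth data.frame (e.g. from the simulator) or a truth VCF
#'   path.
#' @param config An [sv_model_config()]; `config$variant` selects the
#'   ablation variant.
#' @param contigs Contigs to use (default: all).
#' @param epochs,patience,lr,batch_size,val_fraction,metrics_path,verbose
#'   Passed to [train_model()].
#' @param min_mapq,min_op Feature extraction thresholds.
#' @return A trained `sv_model`.
#' @export
sv_train <- function(bam, truth, config = sv_model_config(), contigs = NULL,
                     epochs = 20L, patience = 3L, lr = 3e-3,
                     batch_size = 32L, val_fraction = 0.2,
                     metrics_path = NULL, min_mapq = 20L, min_op = 30L,
                     verbose = FALSE) {
  if (is.character(truth)) truth <- read_truth_vcf(truth)
  lens <- bam_contig_lengths(bam)
  if (is.null(contigs)) contigs <- names(lens)
  ws_list <- list(); labels <- list(); covs <- c()
  for (cg in contigs) {
    if (verbose) log_msg("features: %s", cg)
    fm <- extract_site_features(bam, list(contig = cg, start = 0L,
                                          end = unname(lens[cg])),
                                min_mapq = min_mapq, min_op = min_op)
    ws <- tile_windows(fm)
    ws_list[[cg]] <- ws
    labels[[cg]] <- label_windows(truth, ws)
    covs <- c(covs, feature_coverage(fm))
  }
  if (sum(unlist(lapply(labels, sum))) == 0L) {
    stop("no positive windows: truth set does not overlap the data")
  }
  ts <- build_training_set(unname(ws_list), unname(labels), mean(covs))
  train_model(ts, config, epochs = epochs, patience = patience, lr = lr,
              batch_size = batch_size, val_fraction = val_fraction,
              metrics_path = metrics_path, verbose = verbose)
}

#' Evaluate a call set against a truth set
#'
#' @param calls Calls VCF path, or a calls data.frame.
#' @param truth Truth VCF path, or a truth data.frame.
#' @param pos_tolerance,len_ratio Matching parameters, see
#'   [evaluate_calls()].
#' @param pass_only Keep only PASS (or unfiltered) call records.
#' @return The [evaluate_calls()] report plus `offset_quartiles` per type.
#' @export
sv_evaluate <- function(calls, truth, pos_tolerance = 500L, len_ratio = 0.7,
                        pass_only = TRUE) {
  if (is.character(calls)) calls <- read_truth_vcf(calls)
  if (is.character(truth)) truth <- read_truth_vcf(truth)
  if (pass_only && !is.null(calls$filter)) {
    calls <- calls[calls$filter %in% c("PASS", ".", NA), , drop = FALSE]
  }
  ev <- evaluate_calls(calls, truth, pos_tolerance, len_ratio)
  ev$offset_quartiles <- lapply(ev$offsets, function(o) {
    if (length(o) == 0L) rep(NA_real_, 3L)
    else stats::quantile(o, c(0.25, 0.5, 0.75), names = FALSE)
  })
  ev
}
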