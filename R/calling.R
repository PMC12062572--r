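# Variant calling from subclusters: a coverage-adaptive minimum-support
# threshold decides whether a subcluster becomes a PASS call, and a vote over
# Bayesian, EM and read-ratio genotypers assigns the genotype (the plain
# likelihood argmax is kept for diagnostics).

GENOTYPES <- c("0/0", "0/1", "1/1")

#' Parameters of the dynamic read-support threshold
#'
#' The minimum supporting-read count for a locus is
#' `ceil(mu * C_global^phi * (1 + rho * tanh((C_local - C_global)/C_global)))`,
#' clamped below at `floor`. When the sample error rate is at least
#' `error_rate_cutoff` or global coverage falls below `low_coverage_cutoff`,
#' the adjusted `mu_adj` / `rho_adj` pair is used instead, relaxing the
#' threshold for noisy or shallow data.
#'
#' @param mu Global adjustment factor (> 0).
#' @param phi Coverage power exponent in (0, 1].
#' @param rho Local coverage deviation factor (>= 0).
#' @param floor Minimum allowed threshold (>= 1).
#' @param error_rate_cutoff Error rate at which the adjusted regime starts.
#' @param low_coverage_cutoff Global coverage below which the adjusted
#'   regime starts.
#' @param mu_adj,rho_adj Adjusted-regime parameters.
#' @return List of class `sv_support_params`.
#' @export
support_params <- function(mu = 1.0, phi = 0.6, rho = 0.4, floor = 2L,
                           error_rate_cutoff = 0.10, low_coverage_cutoff = 10,
                           mu_adj = 0.8, rho_adj = 0.3) {
  stopifnot(mu > 0, phi > 0, phi <= 1, rho >= 0, floor >= 1)
  structure(list(mu = mu, phi = phi, rho = rho, floor = as.integer(floor),
                 error_rate_cutoff = error_rate_cutoff,
                 low_coverage_cutoff = low_coverage_cutoff,
                 mu_adj = mu_adj, rho_adj = rho_adj),
            class = "sv_support_params")
}

#' Dynamic minimum supporting-read threshold
#'
#' @param c_global Global mean coverage (> 0).
#' @param c_local Local coverage at the variant region (>= 0).
#' @param params A [support_params()].
#' @param error_rate Sample mean read error rate.
#' @return Integer threshold.
#' @export
min_support <- function(c_global, c_local, params = support_params(),
                        error_rate = 0) {
  if (c_global <= 0) stop("c_global must be positive")
  if (c_local < 0) stop("c_local must be non-negative")
  adjusted <- error_rate >= params$error_rate_cutoff ||
    c_global < params$low_coverage_cutoff
  mu <- if (adjusted) params$mu_adj else params$mu
  rho <- if (adjusted) params$rho_adj else params$rho
  raw <- mu * c_global^params$phi *
    (1 + rho * tanh((c_local - c_global) / c_global))
  max(as.integer(ceiling(raw)), params$floor)
}

#' Genotype log-likelihoods from read support
#'
#' Binomial model: the probability that a read at the locus shows the variant
#' is `epsilon` under 0/0, 1/2 under 0/1 and `1 - epsilon` under 1/1.
#'
#' @param ref_support Reads spanning the locus without the variant.
#' @param alt_support Reads carrying the variant.
#' @param epsilon Locus error rate in (0, 0.5).
#' @return Named numeric vector of log-likelihoods for 0/0, 0/1, 1/1.
#' @export
genotype_likelihoods <- function(ref_support, alt_support, epsilon = 0.1) {
  stopifnot(ref_support >= 0, alt_support >= 0, epsilon > 0, epsilon < 0.5)
  n <- ref_support + alt_support
  if (n == 0L) stop("no supporting reads; genotype is undetermined (./.)")
  ll <- stats::dbinom(alt_support, n, c(epsilon, 0.5, 1 - epsilon), log = TRUE)
  names(ll) <- GENOTYPES
  ll
}

#' Bayesian genotype call
#'
#' @param loglik Log-likelihoods from [genotype_likelihoods()].
#' @param priors Prior probabilities for 0/0, 0/1, 1/1 (sum to 1).
#' @return List with `genotype` and `posterior` (named, sums to 1).
#' @export
genotype_bayes <- function(loglik, priors = c(0.4, 0.4, 0.2)) {
  stopifnot(length(priors) == 3L, abs(sum(priors) - 1) < 1e-8)
  lp <- loglik + log(priors)
  m <- max(lp)
  w <- exp(lp - m)
  z <- sum(w)
  if (!is.finite(z) || z <= 0) stop("zero posterior normalisation constant")
  post <- w / z
  names(post) <- GENOTYPES
  list(genotype = GENOTYPES[which.max(post)], posterior = post)
}

#' EM genotype estimate
#'
#' Starting from uniform genotype weights, the E-step computes the
#' responsibility of each genotype for the observed support counts under the
#' binomial emission model and the M-step adopts the responsibilities as the
#' new weights, iterating until the largest weight change falls below `tol`.
#' The weights remain a probability vector at every iteration and converge to
#' the maximum-likelihood genotype.
#'
#' @param ref_support,alt_support,epsilon As in [genotype_likelihoods()].
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the weights.
#' @return List with `genotype`, `weights` (named probability vector) and
#'   `converged`.
#' @export
genotype_em <- function(ref_support, alt_support, epsilon = 0.1,
                        max_iter = 100L, tol = 1e-6) {
  ll <- genotype_likelihoods(ref_support, alt_support, epsilon)
  lik <- exp(ll - max(ll))
  w <- rep(1 / 3, 3L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    resp <- w * lik
    resp <- resp / sum(resp)
    if (max(abs(resp - w)) < tol) { w <- resp; converged <- TRUE; break }
    w <- resp
  }
  names(w) <- GENOTYPES
  list(genotype = GENOTYPES[which.max(w)], weights = w, converged = converged)
}

#' Read-support ratio genotype
#'
#' Reference-allele fraction above `threshold` gives 0/0, variant fraction
#' above it gives 1/1, anything balanced gives 0/1.
#'
#' @param ref_support,alt_support Read counts (total > 0).
#' @param threshold Ratio threshold.
#' @return Genotype string.
#' @export
genotype_ratio <- function(ref_support, alt_support, threshold = 0.7) {
  n <- ref_support + alt_support
  if (n == 0L) stop("no supporting reads")
  rf <- ref_support / n
  if (rf > threshold) "0/0" else if (1 - rf > threshold) "1/1" else "0/1"
}

#' Majority vote over the three genotyping methods
#'
#' @param bayes,em,ratio Genotype strings from the three methods.
#' @return The majority genotype; on a three-way tie the Bayesian call wins
#'   (it already integrates the prior and is deterministic).
#' @export
genotype_vote <- function(bayes, em, ratio) {
  votes <- c(bayes, em, ratio)
  tab <- table(votes)
  if (max(tab) == 1L) return(bayes)
  names(tab)[which.max(tab)]
}

genotype_locus <- function(ref_support, alt_support, epsilon = 0.1,
                           priors = c(0.4, 0.4, 0.2), ratio_threshold = 0.7) {
  if (ref_support + alt_support == 0L) {
    return(list(genotype = "./.", bayes = NA_character_, em = NA_character_,
                ratio = NA_character_, likelihood = NA_character_))
  }
  ll <- genotype_likelihoods(ref_support, alt_support, epsilon)
  gb <- genotype_bayes(ll, priors)
  ge <- genotype_em(ref_support, alt_support, epsilon)
  gr <- genotype_ratio(ref_support, alt_support, ratio_threshold)
  list(genotype = genotype_vote(gb$genotype, ge$genotype, gr),
       bayes = gb$genotype, em = ge$genotype, ratio = gr,
       likelihood = GENOTYPES[which.max(ll)])
}

#' Call variants from subclusters
#'
#' Support is the number of distinct reads contributing a signature to the
#' subcluster; a call is PASS when support reaches the dynamic minimum and
#' (for intra-contig types) the length reaches `min_svlen`. Filtered records
#' are retained with a filter label.
#'
#' @param subclusters List from [cluster_signatures()].
#' @param coverage List with `global` (mean coverage), `local` (function of
#'   contig, start, end returning local mean coverage) and optionally
#'   `ref_count` (function of contig, start, end, exclude_reads returning
#'   reads spanning the locus without the variant).
#' @param params A [support_params()].
#' @param error_rate Sample mean read error rate.
#' @param epsilon Locus error rate for genotyping.
#' @param priors Genotype priors for the Bayesian method.
#' @param min_svlen Minimum PASS length for non-breakend calls (bp).
#' @return data.frame of calls (class `sv_calls`).
#' @export
call_variants <- function(subclusters, coverage, params = support_params(),
                          error_rate = 0, epsilon = 0.1,
                          priors = c(0.4, 0.4, 0.2), min_svlen = 50L) {
  rows <- lapply(subclusters, function(sc) {
    support <- length(unique(sc$members$read))
    end <- if (sc$svtype %in% c("DEL", "DUP", "INV")) sc$pos + sc$len else sc$pos
    c_local <- coverage$local(sc$contig, sc$pos, max(end, sc$pos + 1L))
    thr <- min_support(coverage$global, c_local, params, error_rate)
    filter <- "PASS"
    if (support < thr) filter <- "LowSupport"
    else if (sc$svtype != "TRA" && sc$len < min_svlen) filter <- "MinLength"
    ref_n <- if (!is.null(coverage$ref_count)) {
      coverage$ref_count(sc$contig, sc$pos, end, unique(sc$members$read))
    } else {
      max(round(c_local) - support, 0L)
    }
    gt <- genotype_locus(ref_n, support, epsilon, priors)
    data.frame(contig = sc$contig, pos = sc$pos, end = end,
               svtype = sc$svtype, svlen = sc$len, support = support,
               min_support = thr,
               genotype = gt$genotype, gt_bayes = gt$bayes, gt_em = gt$em,
               gt_ratio = gt$ratio, gt_likelihood = gt$likelihood,
               filter = filter,
               mate_contig = if (sc$svtype == "TRA") sc$mate_contig else NA_character_,
               mate_pos = if (sc$svtype == "TRA") sc$mate_pos else NA_integer_,
               stringsAsFactors = FALSE)
  })
  calls <- if (length(rows) == 0L) empty_calls() else do.call(rbind, rows)
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("sv_calls", "data.frame")
  calls
}

empty_calls <- function() {
  data.frame(contig = character(0), pos = integer(0), end = integer(0),
             svtype = character(0), svlen = integer(0), support = integer(0),
             min_support = integer(0), genotype = character(0),
             gt_bayes = character(0), gt_em = character(0),
             gt_ratio = character(0), gt_likelihood = character(0),
             filter = character(0), mate_contig = character(0),
             mate_pos = integer(0), stringsAsFactors = FALSE)
}
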