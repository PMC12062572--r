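# Dynamic support threshold and the voting genotyper.

test_that("support threshold reduces to ceil(mu * c^phi) at balanced coverage", {
  p <- support_params()
  for (c in c(5, 10, 30, 70)) {
    mu <- if (c < p$low_coverage_cutoff) p$mu_adj else p$mu
    expect_equal(min_support(c, c, p, error_rate = 0.05),
                 max(as.integer(ceiling(mu * c^p$phi)), p$floor))
  }
  # worked value: mu 1, phi 0.6, c 30 -> ceil(30^0.6) = ceil(7.696) = 8
  expect_equal(min_support(30, 30, p, error_rate = 0.05), 8L)
  expect_error(min_support(0, 10, p), "positive")
  expect_error(min_support(10, -1, p), "non-negative")
})

test_that("support threshold is monotone in local coverage and bounded by rho", {
  p <- support_params()
  prev <- 0L
  for (cl in seq(0, 120, by = 5)) {
    thr <- min_support(30, cl, p, error_rate = 0.05)
    expect_gte(thr, prev)
    prev <- thr
    base <- p$mu * 30^p$phi
    expect_gte(thr, base * (1 - p$rho) - 1)
    expect_lte(thr, ceiling(base * (1 + p$rho)))
  }
  # high error rate switches to the relaxed parameter set
  expect_equal(min_support(30, 30, p, error_rate = 0.15),
               as.integer(ceiling(p$mu_adj * 30^p$phi)))
})

test_that("genotype likelihoods match a direct binomial computation", {
  for (case in list(c(20, 0), c(10, 10), c(3, 27), c(0, 25))) {
    ref <- case[1]; alt <- case[2]; n <- ref + alt; eps <- 0.1
    ll <- genotype_likelihoods(ref, alt, eps)
    for (k in 1:3) {
      pgt <- c(eps, 0.5, 1 - eps)[k]
      manual <- lchoose(n, alt) + alt * log(pgt) + ref * log(1 - pgt)
      expect_equal(unname(ll[k]), manual, tolerance = 1e-9)
    }
  }
  expect_equal(names(which.max(genotype_likelihoods(20, 0, 0.1))), "0/0")
  expect_equal(names(which.max(genotype_likelihoods(10, 10, 0.1))), "0/1")
  expect_error(genotype_likelihoods(0, 0, 0.1), "undetermined")
})

test_that("Bayesian genotyping integrates priors correctly", {
  ll <- genotype_likelihoods(10, 10, 0.1)
  flat <- genotype_bayes(ll, c(1, 1, 1) / 3)
  expect_equal(flat$genotype, names(which.max(ll)))
  expect_equal(sum(flat$posterior), 1, tolerance = 1e-12)
  # a strong reference prior flips a weak-evidence heterozygous call
  ll2 <- genotype_likelihoods(3, 2, 0.1)
  expect_equal(genotype_bayes(ll2, c(1, 1, 1) / 3)$genotype, "0/1")
  expect_equal(genotype_bayes(ll2, c(0.98, 0.01, 0.01))$genotype, "0/0")
})

test_that("EM converges to the maximum-likelihood genotype", {
  em <- genotype_em(0, 25, 0.05)
  expect_true(em$converged)
  expect_equal(em$genotype, "1/1")
  expect_gt(em$weights[["1/1"]], 0.99)
  expect_equal(sum(em$weights), 1, tolerance = 1e-12)
  expect_true(all(em$weights >= 0))
  # exhaustive small grid: EM argmax equals the flat-prior Bayesian argmax
  for (n in c(5, 12, 25, 40)) {
    for (alt in 0:n) {
      ref <- n - alt
      em <- genotype_em(ref, alt, 0.1)
      fb <- genotype_bayes(genotype_likelihoods(ref, alt, 0.1), c(1, 1, 1) / 3)
      expect_equal(em$genotype, fb$genotype,
                   label = sprintf("ref=%d alt=%d", ref, alt))
    }
  }
})

test_that("read-ratio genotyping applies the 0.7 threshold symmetrically", {
  expect_equal(genotype_ratio(8, 2), "0/0")
  expect_equal(genotype_ratio(2, 8), "1/1")
  expect_equal(genotype_ratio(5, 5), "0/1")
  expect_equal(genotype_ratio(7, 3), "0/1")   # exactly at threshold stays het
})

test_that("the vote takes the majority and breaks ties toward Bayes", {
  expect_equal(genotype_vote("0/1", "0/1", "0/0"), "0/1")
  expect_equal(genotype_vote("1/1", "1/1", "1/1"), "1/1")
  expect_equal(genotype_vote("0/0", "0/1", "1/1"), "0/0")
})

test_that("all three methods agree on unambiguous evidence", {
  for (n in c(10, 20, 40)) {
    for (eps in c(0.05, 0.1)) {
      ll0 <- genotype_likelihoods(n, 0, eps)
      expect_equal(genotype_bayes(ll0)$genotype, "0/0")
      expect_equal(genotype_em(n, 0, eps)$genotype, "0/0")
      expect_equal(genotype_ratio(n, 0), "0/0")
      ll1 <- genotype_likelihoods(0, n, eps)
      expect_equal(genotype_bayes(ll1)$genotype, "1/1")
      expect_equal(genotype_em(0, n, eps)$genotype, "1/1")
      expect_equal(genotype_ratio(0, n), "1/1")
    }
  }
})

test_that("voting genotyper recovers simulated genotypes accurately", {
  set.seed(808)
  n <- 30L; eps <- 0.08
  correct <- 0L; total <- 0L
  for (g in c("0/0", "0/1", "1/1")) {
    p_alt <- c(`0/0` = eps, `0/1` = 0.5, `1/1` = 1 - eps)[[g]]
    alt <- rbinom(300L, n, p_alt)
    for (a in alt) {
      gt <- svscout:::genotype_locus(n - a, a, eps)
      correct <- correct + (gt$genotype == g)
      total <- total + 1L
    }
  }
  expect_gt(correct / total, 0.95)
})

test_that("call_variants applies the support filter and length floor", {
  mk_sub <- function(svtype, pos, len, n_reads) {
    list(svtype = svtype, contig = "A", pos = pos, len = len,
         members = data.frame(read = paste0("r", seq_len(n_reads)),
                              error_rate = 0.1))
  }
  coverage <- list(global = 30, local = function(...) 30)
  calls <- call_variants(list(mk_sub("DEL", 1000L, 400L, 12L),
                              mk_sub("DEL", 9000L, 400L, 3L),
                              mk_sub("INS", 20000L, 40L, 12L)),
                         coverage)
  expect_equal(calls$filter, c("PASS", "LowSupport", "MinLength"))
  expect_equal(calls$min_support, rep(8L, 3))   # ceil(30^0.6)
  expect_true(all(calls$support[calls$filter == "PASS"] >=
                    calls$min_support[calls$filter == "PASS"]))
  expect_equal(nrow(call_variants(list(), coverage)), 0L)
})
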