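# Toy locus: few alleles, so the joint genotype posterior is exactly
# enumerable and the Gibbs sampler can be checked against brute force.
toy_locus_peaks <- function(heights, alleles, locus = "TPOX") {
  geom <- pgmix:::panel_locus(pp_panel, locus)
  peak_table(data.frame(
    sample = "toy", locus = locus, dye = geom$dye, allele = alleles,
    size_bp = pgmix:::allele_size_bp(geom, alleles), height_rfu = heights,
    injection_s = 5))
}

test_that("MCMC marginals match brute-force enumeration on a toy mixture", {
  freqs <- toy_freqs(c("8", "9", "10", "11"), c(0.3, 0.3, 0.2, 0.2))
  pk <- toy_locus_peaks(c(700, 700, 280, 310), c("8", "10", "9", "11"))
  pars <- model_params(weights = c(0.7, 0.3), mass = 2000, stutter_rate = 0.05)
  oracle <- enumerate_genotype_posterior(pk, pars, freqs, pp_panel,
                                         theta = 0.01)
  fit <- quiet_infer(pk, inference_settings(
    2, iterations = 4000, burn_in = 500, seed = 5,
    fix_weights = c(0.7, 0.3), fix_mass = 2000,
    sample_stutter = FALSE, sample_variance = FALSE),
    freqs, pp_panel, params = pars)
  n_rec <- fit$diagnostics$recorded
  for (k in 1:2) {
    got <- fit$posteriors[[k]][["TPOX"]]
    want <- oracle[[k]][["TPOX"]]
    top <- which.max(want$prob)
    tol <- max(3 * sqrt(want$prob[top] * (1 - want$prob[top]) / n_rec), 0.01)
    expect_equal(got$a1, want$a1)
    expect_lt(max(abs(got$prob - want$prob)), tol)
  }
})

test_that("inference is a deterministic function of the seed", {
  mix <- make_mixture(21)
  s <- inference_settings(2, iterations = 400, burn_in = 100, seed = 9)
  f1 <- quiet_infer(mix$peaks, s, pp_freqs, pp_panel)
  f2 <- quiet_infer(mix$peaks, s, pp_freqs, pp_panel)
  expect_identical(f1$posteriors, f2$posteriors)
  expect_identical(f1$weights, f2$weights)
})

test_that("single-source profiles resolve to the true genotype everywhere", {
  prof <- with_test_seed(8, random_profile(pp_freqs, pp_panel, "single"))
  spec <- mixture_spec(list(prof), 1, cv = 0.05)
  pk <- simulate_profile(spec, pp_panel, seed = 88)
  fit <- quiet_infer(pk, inference_settings(1, iterations = 600,
                                            burn_in = 200, seed = 4),
                     pp_freqs, pp_panel)
  for (loc in fit$loci) {
    d <- fit$posteriors[[1]][[loc]]
    expect_identical(mode_pair(d), prof$genotypes[[loc]])
    expect_gte(max(d$prob), 0.99)
  }
})

test_that("the minor contributor of a 2:1 mixture concentrates on its pair", {
  # four-allele pattern 600/600/300/300: the minor genotype is 10,12
  freqs <- toy_freqs(c("7", "10", "12", "14"), c(0.21, 0.08, 0.17, 0.14),
                     locus = "PENTA E")
  pk <- toy_locus_peaks(c(600, 300, 300, 600), c("7", "10", "12", "14"),
                        locus = "PENTA E")
  fit <- quiet_infer(pk, inference_settings(2, iterations = 3000,
                                            burn_in = 1000, seed = 6),
                     freqs, pp_panel)
  minor <- fit$posteriors[[2]][["PENTA E"]]
  expect_identical(mode_pair(minor), c("10", "12"))
  expect_gte(gd_prob(minor, "10", "12"), 0.93)
  major <- fit$posteriors[[1]][["PENTA E"]]
  expect_identical(mode_pair(major), c("7", "14"))
  expect_equal(fit$weights$mean[1], 2 / 3, tolerance = 0.05)
})

test_that("weight posteriors recover the true mixture proportions", {
  mix <- make_mixture(22, w_major = 0.7, cv = 0)
  fit <- quiet_infer(mix$peaks,
                     inference_settings(2, iterations = 1200, burn_in = 400,
                                        seed = 3), pp_freqs, pp_panel)
  expect_equal(unname(fit$weights$mean), c(0.7, 0.3), tolerance = 0.05)
  expect_true(all(abs(rowSums(fit$weights$samples) - 1) < 1e-9))
})

test_that("assumed contributors stay pinned to their known genotypes", {
  mix <- make_mixture(23, w_major = 0.6)
  fit <- quiet_infer(mix$peaks, inference_settings(
    2, iterations = 400, burn_in = 100, seed = 2,
    assumed = list(mix$major)), pp_freqs, pp_panel)
  for (loc in fit$loci) {
    d <- fit$posteriors[[1]][[loc]]
    expect_identical(mode_pair(d), mix$major$genotypes[[loc]])
    expect_equal(max(d$prob), 1)
  }
})

test_that("contributor-count utilities behave", {
  mix <- make_mixture(24)
  k <- suggest_contributor_count(mix$peaks)
  expect_gte(k, 2)
  expect_error(inference_settings(2, iterations = 100, burn_in = 100),
               "burn_in")
  expect_error(inference_settings(0), ">= 1")
  expect_error(quiet_infer(mix$peaks[0, ],
                           inference_settings(2, iterations = 100,
                                              burn_in = 10, seed = 1),
                           pp_freqs, pp_panel),
               "empty")
})

test_that("genotype KL divergence is a base-10 divergence", {
  u <- build_prior_distribution("PENTA E", pp_freqs, 0)
  expect_equal(genotype_kl(u, u), 0)
  # point mass against a uniform distribution over 210 pairs: log10(210)
  unif <- genotype_dist("PENTA E", u$a1, u$a2, rep(1 / nrow(u), nrow(u)))
  pt <- genotype_dist("PENTA E", "10", "12", 1)
  expect_equal(genotype_kl(pt, unif), log10(210))
  # asymmetry on a crafted pair
  p <- genotype_dist("TPOX", c("8", "9"), c("8", "9"), c(0.9, 0.1))
  q <- genotype_dist("TPOX", c("8", "9"), c("8", "9"), c(0.5, 0.5))
  expect_false(isTRUE(all.equal(genotype_kl(p, q), genotype_kl(q, p))))
  expect_gte(genotype_kl(p, q), 0)
  # support violation errors
  expect_error(genotype_kl(genotype_dist("TPOX", "7", "7", 1), q), "support")
})

test_that("replicate runs agree and under-run chains are flagged", {
  mix <- make_mixture(25, w_major = 0.75, cv = 0.05)
  s1 <- inference_settings(2, iterations = 1200, burn_in = 400, seed = 11)
  s2 <- inference_settings(2, iterations = 1200, burn_in = 400, seed = 77)
  f1 <- quiet_infer(mix$peaks, s1, pp_freqs, pp_panel)
  f2 <- quiet_infer(mix$peaks, s2, pp_freqs, pp_panel)
  cc <- check_concordance(f1, f2, tolerance = 0.05)
  expect_true(cc$pass)
  expect_identical(check_concordance(f1, f1)$kl[, 1],
                   setNames(rep(0, length(f1$loci)), f1$loci))
  # a deliberately truncated chain does not replicate the long run
  short <- quiet_infer(mix$peaks,
                       inference_settings(2, iterations = 12, burn_in = 2,
                                          seed = 5), pp_freqs, pp_panel)
  cc2 <- check_concordance(f1, short, tolerance = 0.05)
  expect_false(cc2$pass)
  # mismatched settings are an error, not a report
  f3 <- quiet_infer(mix$peaks, inference_settings(3, iterations = 200,
                                                  burn_in = 50, seed = 1),
                    pp_freqs, pp_panel)
  expect_error(check_concordance(f1, f3), "mismatched")
})
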