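panel_locus <- function(loc) pgmix:::panel_locus(pp_panel, loc)

fig_peaks <- function(heights = c(600, 300, 300, 600),
                      alleles = c("7", "10", "12", "14")) {
  peak_table(data.frame(
    sample = "ex", locus = "PENTA E", dye = "blue", allele = alleles,
    size_bp = 354 + 5 * as.numeric(alleles), height_rfu = heights,
    injection_s = 5))
}

test_that("mean patterns are weighted sums of contributor allele pairs", {
  geom <- panel_locus("PENTA E")
  pars <- model_params(weights = c(2 / 3, 1 / 3), mass = 1800,
                       stutter_rate = 0)
  mu <- mean_pattern(list(c("7", "14"), c("10", "12")), pars, geom)
  expect_equal(mu[c("7", "10", "12", "14")],
               c(`7` = 600, `10` = 300, `12` = 300, `14` = 600))
  # single homozygote contributor concentrates the whole mass in one peak
  mu2 <- mean_pattern(list(c("10", "10")),
                      model_params(weights = 1, mass = 1000, stutter_rate = 0),
                      geom)
  expect_equal(mu2, c(`10` = 1000))
  # a shared allele receives the sum of both contributors' half-doses
  mu3 <- mean_pattern(list(c("7", "10"), c("10", "12")),
                      model_params(weights = c(0.5, 0.5), mass = 1200,
                                   stutter_rate = 0), geom)
  expect_equal(unname(mu3["10"]), 600)
  # linear in mass; invariant under permutation of equal-weight contributors
  expect_equal(2 * mu3,
               mean_pattern(list(c("7", "10"), c("10", "12")),
                            model_params(weights = c(0.5, 0.5), mass = 2400,
                                         stutter_rate = 0), geom))
  expect_equal(mu3, mean_pattern(list(c("10", "12"), c("7", "10")),
                                 model_params(weights = c(0.5, 0.5),
                                              mass = 1200, stutter_rate = 0),
                                 geom))
})

test_that("the model mean equals the noise-free simulator output", {
  mix <- make_mixture(31, w_major = 0.65, cv = 0)
  spec <- mix$spec
  pars <- model_params(weights = spec$weights, mass = spec$total_mass,
                       stutter_rate = spec$stutter_rate,
                       degradation_rate = spec$degradation_rate)
  pk <- simulate_profile(mixture_spec(list(mix$major, mix$minor),
                                      spec$weights, cv = 0),
                         pp_panel, seed = 1, detection_floor = 0)
  for (loc in c("TPOX", "PENTA E", "FGA")) {
    rows <- pk[pk$locus == loc, ]
    mu <- mean_pattern(list(mix$major$genotypes[[loc]],
                            mix$minor$genotypes[[loc]]),
                       pars, panel_locus(loc))
    expect_equal(setNames(rows$height_rfu, rows$allele)[names(mu)], mu)
  }
})

test_that("the locus log-likelihood matches the univariate closed form", {
  pars <- model_params(weights = 1, mass = 900, stutter_rate = 0,
                       variance_scale = 5, variance_floor = 100)
  pk <- fig_peaks(heights = 850, alleles = "10")
  ll <- log_likelihood(pk, list(c("10", "10")), pars,
                       panel_locus("PENTA E"))
  v <- 100 + 5 * 900
  expect_equal(ll, -0.5 * log(2 * pi * v) - (850 - 900)^2 / (2 * v))
  # data equal to the mean pattern sits at the Gaussian mode
  pk2 <- fig_peaks(heights = 900, alleles = "10")
  expect_equal(log_likelihood(pk2, list(c("10", "10")), pars,
                              panel_locus("PENTA E")),
               -0.5 * log(2 * pi * v))
  # empty locus is flagged, not an error
  expect_true(is.na(log_likelihood(pk[0, ], list(c("10", "10")), pars,
                                   panel_locus("PENTA E"))))
})

test_that("the true genotype combination explains the data best", {
  pars <- model_params(weights = c(2 / 3, 1 / 3), mass = 1800,
                       stutter_rate = 0)
  pk <- fig_peaks()
  geom <- panel_locus("PENTA E")
  ll_true <- log_likelihood(pk, list(c("7", "14"), c("10", "12")), pars, geom)
  ll_alt <- log_likelihood(pk, list(c("7", "10"), c("12", "14")), pars, geom)
  ll_alt2 <- log_likelihood(pk, list(c("7", "10"), c("12", "15")), pars, geom)
  expect_gt(ll_true, ll_alt)
  expect_gt(ll_true, ll_alt2)
})

test_that("consistent rescaling shifts the log-likelihood by the Jacobian", {
  pars <- model_params(weights = c(0.5, 0.5), mass = 1000, stutter_rate = 0,
                       variance_scale = 5, variance_floor = 100)
  pk <- fig_peaks(heights = c(480, 520, 260, 240))
  geom <- panel_locus("PENTA E")
  g <- list(c("7", "14"), c("10", "12"))
  ll <- log_likelihood(pk, g, pars, geom)
  c_ <- 3
  pk2 <- fig_peaks(heights = c_ * c(480, 520, 260, 240))
  pars2 <- model_params(weights = c(0.5, 0.5), mass = c_ * 1000,
                        stutter_rate = 0, variance_scale = c_ * 5,
                        variance_floor = c_^2 * 100)
  expect_equal(log_likelihood(pk2, g, pars2, geom), ll - 4 * log(c_),
               tolerance = 1e-12)
})

test_that("joint log posteriors add likelihoods and log priors across loci", {
  pars <- model_params(weights = c(2 / 3, 1 / 3), mass = 1800,
                       stutter_rate = 0)
  pk <- fig_peaks()
  prior <- build_prior_distribution("PENTA E", pp_freqs, 0.01)
  g <- list(`PENTA E` = list(c("7", "14"), c("10", "12")))
  jlp <- joint_log_posterior(pk, g, pars, list(`PENTA E` = prior), pp_panel)
  ll <- log_likelihood(pk, g[[1]], pars, panel_locus("PENTA E"))
  expect_equal(jlp, ll + log(gd_prob(prior, "7", "14")) +
                 log(gd_prob(prior, "10", "12")))
  # doubling one pair's prior raises the joint log posterior by log 2
  doubled <- prior
  i <- which(doubled$a1 == "10" & doubled$a2 == "12")
  p <- doubled$prob; p[i] <- 2 * p[i]
  doubled <- genotype_dist("PENTA E", doubled$a1, doubled$a2, p / sum(p))
  jlp2 <- joint_log_posterior(pk, g, pars, list(`PENTA E` = doubled), pp_panel)
  expect_equal(jlp2 - jlp, log(2) - 2 * log(sum(p)), tolerance = 1e-10)
  # zero prior at a hypothesized pair rejects the hypothesis
  expect_equal(joint_log_posterior(
    pk, list(`PENTA E` = list(c("7", "14"), c("20", "21"))), pars,
    list(`PENTA E` = genotype_dist("PENTA E", "7", "14", 1)), pp_panel),
    -Inf)
})

test_that("two-hypothesis posteriors match direct enumeration", {
  pars <- model_params(weights = c(2 / 3, 1 / 3), mass = 1800,
                       stutter_rate = 0)
  pk <- fig_peaks()
  prior <- build_prior_distribution("PENTA E", pp_freqs, 0)
  hyps <- list(list(`PENTA E` = list(c("7", "14"), c("10", "12"))),
               list(`PENTA E` = list(c("7", "10"), c("12", "14"))))
  lp <- vapply(hyps, joint_log_posterior, 0, peaks = pk, params = pars,
               priors = list(`PENTA E` = prior), panel = pp_panel)
  post <- exp(lp - max(lp)); post <- post / sum(post)
  # brute-force oracle: likelihood x prior computed from first principles
  dens <- function(g) {
    mu <- mean_pattern(g, pars, panel_locus("PENTA E"))
    v <- 100 + 5 * mu
    d <- setNames(pk$height_rfu, pk$allele)[names(mu)]
    prod(dnorm(d, mu, sqrt(v))) *
      gd_prob(prior, g[[1]][1], g[[1]][2]) *
      gd_prob(prior, g[[2]][1], g[[2]][2])
  }
  brute <- vapply(list(hyps[[1]][[1]], hyps[[2]][[1]]), dens, 0)
  expect_equal(post, brute / sum(brute), tolerance = 1e-9)
})
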