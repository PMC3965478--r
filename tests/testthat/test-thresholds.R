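green_peaks <- function(heights, alleles = as.character(seq_along(heights)),
                        injection = 5, locus = "D5S818", dye = "green") {
  peak_table(data.frame(
    sample = "s", locus = locus, dye = dye, allele = alleles,
    size_bp = 100 + 4 * as.numeric(alleles), height_rfu = heights,
    injection_s = injection))
}

test_that("analytical thresholds call alleles per dye channel", {
  pk <- green_peaks(c(600, 300, 300, 600, 40), c("8", "9", "10", "11", "12"))
  calls <- call_alleles(pk)
  expect_equal(nrow(calls), 4)  # the 40 RFU peak is below 84 (green)
  expect_false("12" %in% calls$allele)
  # stochastic marking at a 5 s injection (threshold 320 RFU)
  expect_equal(setNames(calls$above_stochastic, calls$allele),
               c(`8` = TRUE, `9` = FALSE, `10` = FALSE, `11` = TRUE))
  # a red-dye peak exactly at its 52 RFU threshold is called (>= rule)
  red <- green_peaks(52, "8", dye = "red")
  expect_equal(nrow(call_alleles(red)), 1)
  expect_equal(nrow(call_alleles(red, threshold_config(strict = TRUE))), 0)
  expect_error(call_alleles(green_peaks(100, "8", dye = "purple")),
               "unknown dye")
  expect_error(threshold_config(analytical_by_dye = c(blue = 400)),
               "stochastic")
})

test_that("raising the analytical threshold never adds calls", {
  pk <- green_peaks(c(90, 150, 400, 700), c("8", "9", "10", "11"))
  base <- threshold_config()
  for (extra in c(0, 20, 100, 400)) {
    cfg <- threshold_config(base$analytical_by_dye + extra,
                            base$stochastic_by_injection + extra)
    expect_true(all(call_alleles(pk, cfg)$allele %in%
                      call_alleles(pk, base)$allele))
  }
})

test_that("inclusion posteriors reproduce the bundled worked example", {
  ex <- penta_e_example()
  calls <- call_alleles(ex$peaks)
  post <- inclusion_posterior(calls, ex$prior)
  got <- setNames(round(100 * post$prob), paste(post$a1, post$a2, sep = "/"))
  expect_equal(got[paste(ex$prior_pairs$a1, ex$prior_pairs$a2, sep = "/")],
               c(`7/7` = 17, `7/10` = 13, `7/12` = 28, `7/14` = 8,
                 `10/10` = 2, `10/12` = 11, `10/14` = 3, `12/12` = 11,
                 `12/14` = 6, `14/14` = 1))
  # stochastic restriction keeps only pairs of the 600 RFU alleles {7, 14}
  stoch <- inclusion_posterior(calls, ex$prior, stochastic_only = TRUE)
  expect_equal(setNames(round(100 * stoch$prob),
                        paste(stoch$a1, stoch$a2, sep = "/")),
               c(`7/7` = 67, `7/14` = 30, `14/14` = 3))
  expect_equal(gd_prob(stoch, "10", "12"), 0)
})

test_that("inclusion posterior renormalization equals brute force", {
  for (loc in c("TPOX", "D5S818")) {
    prior <- build_prior_distribution(loc, pp_freqs, 0.01)
    alleles <- locus_frequencies(pp_freqs, loc)
    called <- names(alleles)[seq_len(4)]
    geom <- pgmix:::panel_locus(pp_panel, loc)
    pk <- peak_table(data.frame(
      sample = "s", locus = loc, dye = geom$dye, allele = called,
      size_bp = pgmix:::allele_size_bp(geom, called),
      height_rfu = 500, injection_s = 5))
    post <- inclusion_posterior(call_alleles(pk), prior)
    keep <- prior$a1 %in% called & prior$a2 %in% called
    expect_equal(nrow(post), sum(keep))
    expect_equal(sum(post$prob), 1, tolerance = 1e-12)
    brute <- prior$prob[keep] / sum(prior$prob[keep])
    expect_equal(post$prob, brute)
  }
  # a single called allele forces a point mass at its homozygote
  one <- green_peaks(500, "9")
  pt <- inclusion_posterior(call_alleles(one),
                            build_prior_distribution("D5S818", pp_freqs, 0))
  expect_equal(nrow(pt), 1)
  expect_equal(gd_prob(pt, "9", "9"), 1)
  # no surviving calls: locus inconclusive
  expect_null(inclusion_posterior(call_alleles(green_peaks(50, "9")),
                                  build_prior_distribution("D5S818",
                                                           pp_freqs, 0)))
})

test_that("CPI inclusion probability is the squared sum of call frequencies", {
  f <- locus_frequencies(pp_freqs, "D5S818")
  all_pk <- green_peaks(rep(500, length(f)), names(f))
  calls <- call_alleles(all_pk)
  expect_equal(cpi_locus_probability(calls, "D5S818", pp_freqs), 1)
  one <- call_alleles(green_peaks(500, "9"))
  expect_equal(cpi_locus_probability(one, "D5S818", pp_freqs),
               unname(f["9"])^2)
  some <- call_alleles(green_peaks(c(500, 400, 300), c("9", "10", "11")))
  expect_equal(cpi_locus_probability(some, "D5S818", pp_freqs),
               sum(f[c("9", "10", "11")])^2)
  # theta = 0 agrees with the restricted-prior formulation exactly
  prior <- build_prior_distribution("D5S818", pp_freqs, 0)
  keep <- prior$a1 %in% some$allele & prior$a2 %in% some$allele
  expect_equal(cpi_locus_probability(some, "D5S818", pp_freqs),
               sum(prior$prob[keep]), tolerance = 1e-12)
  expect_error(cpi_locus_probability(call_alleles(green_peaks(50, "9")),
                                     "D5S818", pp_freqs), "no called")
})

test_that("the mCPI stochastic rule drops loci with intermediate peaks", {
  # 600/600/300/300 at 5 s: the 300 RFU calls sit below 320 RFU
  pk <- green_peaks(c(600, 600, 300, 300), c("8", "9", "10", "11"))
  calls <- call_alleles(pk)
  expect_false(mcpi_locus_usable(calls, "D5S818"))
  # all calls above 460 at a 10 s injection: usable
  pk10 <- green_peaks(c(600, 600, 500, 480), c("8", "9", "10", "11"),
                      injection = 10)
  expect_true(mcpi_locus_usable(call_alleles(pk10), "D5S818"))
  # no calls at all: unusable
  expect_false(mcpi_locus_usable(call_alleles(green_peaks(50, "9")),
                                 "D5S818"))
})

test_that("inclusion matches follow the CPI and mCPI locus rules", {
  ref <- contributor_profile("poi", list(D5S818 = c("9", "10")))
  pk <- green_peaks(c(600, 600, 300, 300), c("8", "9", "10", "11"))
  calls <- call_alleles(pk)
  cpi <- inclusion_match(calls, ref, pp_freqs, "cpi")
  f <- locus_frequencies(pp_freqs, "D5S818")
  expect_equal(cpi$combined_lr, 1 / sum(f[c("8", "9", "10", "11")])^2)
  expect_equal(cpi$classification, "include")
  expect_gte(cpi$log10_lr, 0)
  # the same locus is dropped by mCPI; nothing remains -> inconclusive
  mcpi <- inclusion_match(calls, ref, pp_freqs, "mcpi")
  expect_equal(mcpi$classification, "inconclusive")
  expect_true(is.na(mcpi$combined_lr))
  # an uncalled reference allele is an exclusion
  ref2 <- contributor_profile("poi", list(D5S818 = c("9", "13")))
  excl <- inclusion_match(calls, ref2, pp_freqs, "cpi")
  expect_equal(excl$classification, "exclude")
})

test_that("mCPI never exceeds CPI and comparator bans are nonnegative", {
  for (seed in c(301, 302, 303)) {
    mix <- make_mixture(seed, w_major = 0.65)
    calls <- call_alleles(mix$peaks)
    cpi <- inclusion_match(calls, mix$major, pp_freqs, "cpi")
    mcpi <- inclusion_match(calls, mix$major, pp_freqs, "mcpi")
    expect_true(all(cpi$per_locus$lr[cpi$per_locus$used] >= 1))
    if (cpi$classification == "include") expect_gte(cpi$log10_lr, 0)
    if (cpi$classification == "include" && mcpi$classification == "include") {
      expect_lte(mcpi$log10_lr, cpi$log10_lr + 1e-9)
      expect_true(all(mcpi$per_locus$used <= cpi$per_locus$used))
    }
  }
})
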