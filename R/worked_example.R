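# Bundled worked example: a two-person mixture at the Penta E locus. A 7,14
# major contributor with twice the DNA of a 10,12 minor gives peaks of about
# 600/600/300/300 RFU at a 5 s injection. The published prior column over
# the ten allele pairs formed from the called alleles {7, 10, 12, 14} is
# bundled so the threshold-method arithmetic can be reproduced exactly.

#' Two-person mixture worked example at Penta E
#'
#' Returns the example's peak table (alleles 7/14 at ~600 RFU, 10/12 at
#' ~300 RFU, blue dye, 5 s injection), the population prior at the locus,
#' and the 10,12 minor reference profile. Only the ten allele pairs formed
#' from the called alleles have published prior mass (summing to 25.3% of
#' the 210-pair universe); the remaining mass is carried by a single
#' catch-all pair labelled `rest`, which every threshold restriction
#' removes, so the restricted arithmetic is exact.
#'
#' @return list with `peaks` ([peak_table()]), `prior_pairs` (data.frame of
#'   a1, a2, prior in percent), `prior` ([genotype_dist()] including the
#'   catch-all pair), and `reference` ([contributor_profile()])
#' @export
penta_e_example <- function() {
  peaks <- peak_table(data.frame(
    sample = "example", locus = "PENTA E", dye = "blue",
    allele = c("7", "10", "12", "14"),
    size_bp = 354 + 5 * c(7, 10, 12, 14),
    height_rfu = c(600, 300, 300, 600), injection_s = 5,
    stringsAsFactors = FALSE))
  prior_pairs <- data.frame(
    a1 = c("7", "7", "7", "7", "10", "10", "10", "12", "12", "14"),
    a2 = c("7", "10", "12", "14", "10", "12", "14", "12", "14", "14"),
    prior_pct = c(4.3, 3.3, 7.1, 1.9, 0.6, 2.7, 0.7, 2.9, 1.6, 0.2),
    stringsAsFactors = FALSE)
  prior <- genotype_dist(
    "PENTA E",
    c(prior_pairs$a1, "rest"), c(prior_pairs$a2, "rest"),
    c(prior_pairs$prior_pct, 100 - sum(prior_pairs$prior_pct)) / 100)
  list(peaks = peaks, prior_pairs = prior_pairs, prior = prior,
       reference = contributor_profile("minor", list(`PENTA E` = c("10", "12"))))
}
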