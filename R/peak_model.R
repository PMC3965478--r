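# Quantitative likelihood: mean peak patterns from hypothesized genotypes /
# weights / mass, and the multivariate-normal likelihood of observed peaks.
# The covariance is diagonal with variance affine in the expected height
# (variance_floor + variance_scale * mean), the minimal heteroscedastic
# choice: peak variance grows with peak height.

#' Model parameters for the peak-pattern likelihood
#'
#' @param weights mixture weights (simplex)
#' @param mass combined allelic fluorescence intensity M (RFU scale), > 0
#' @param stutter_rate back-stutter fraction in \[0, 0.3)
#' @param degradation_rate exponential decay per 100 bp, >= 0
#' @param variance_scale per-peak variance per unit mean height (RFU), > 0
#' @param variance_floor baseline per-peak variance (RFU^2), > 0
#' @return object of class `model_params`
#' @export
model_params <- function(weights = 1, mass = 3000, stutter_rate = 0.05,
                         degradation_rate = 0, variance_scale = 5,
                         variance_floor = 100) {
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_input("weights must be a valid simplex")
  }
  if (mass <= 0) stop_input("mass must be > 0")
  if (stutter_rate < 0 || stutter_rate >= 0.3) {
    stop_input("stutter_rate must lie in [0, 0.3)")
  }
  if (degradation_rate < 0) stop_input("degradation_rate must be >= 0")
  if (variance_scale <= 0 || variance_floor <= 0) {
    stop_input("variance_scale and variance_floor must be > 0")
  }
  structure(list(weights = weights, mass = mass, stutter_rate = stutter_rate,
                 degradation_rate = degradation_rate,
                 variance_scale = variance_scale,
                 variance_floor = variance_floor),
            class = "model_params")
}

# per-allele unit contribution over a grid of allele labels: degradation
# decay at the parent size, with the stutter fraction moved one repeat down.
# Returns matrix [length(alleles) x length(grid)].
allele_contribution <- function(alleles, grid, geom, stutter_rate,
                                degradation_rate) {
  decay <- exp(-degradation_rate * allele_size_bp(geom, alleles) / 100)
  A <- matrix(0, length(alleles), length(grid),
              dimnames = list(alleles, grid))
  pos <- match(alleles, grid)
  A[cbind(seq_along(alleles), pos)] <- (1 - stutter_rate) * decay
  spos <- match(stutter_allele(alleles), grid)
  ok <- !is.na(spos)
  if (any(ok)) {
    idx <- cbind(which(ok), spos[ok])
    A[idx] <- A[idx] + stutter_rate * decay[ok]
  }
  A
}

# grid for a single evaluation: observed positions + hypothesized alleles +
# their back-stutter positions
build_grid <- function(observed_alleles, hyp_alleles, stutter_rate) {
  g <- union(as.character(observed_alleles), as.character(hyp_alleles))
  if (stutter_rate > 0) g <- union(g, stutter_allele(as.character(hyp_alleles)))
  order_alleles(g)
}

#' Mean peak-height pattern for a genotype hypothesis
#'
#' Constructs the expected peak pattern as a weighted sum of contributor
#' allele pairs: height at allele a is
#' `mass * sum_k w_k * dose_k(a)/2 * decay(size_a)`, with the stutter
#' fraction moved to the (repeat - 1) position. Linear in mass; invariant
#' under permutation of equal-weight contributors.
#'
#' @param genotypes list of allele pairs, one per contributor
#' @param params a [model_params()]
#' @param geom locus geometry (`panel_locus(panel, locus)`)
#' @param grid optional allele grid; defaults to the hypothesis' own grid
#' @return named numeric vector of expected heights (RFU)
#' @export
mean_pattern <- function(genotypes, params, geom, grid = NULL) {
  if (length(genotypes) != length(params$weights)) {
    stop_input("one genotype pair per contributor is required")
  }
  hyp <- unique(unlist(genotypes))
  grid <- grid %||% build_grid(character(0), hyp, params$stutter_rate)
  A <- allele_contribution(order_alleles(hyp), grid, geom,
                           params$stutter_rate, params$degradation_rate)
  mu <- numeric(length(grid))
  for (k in seq_along(genotypes)) {
    g <- canonical_pair(genotypes[[k]][1], genotypes[[k]][2])
    mu <- mu + params$weights[k] * (A[g[1], ] + A[g[2], ]) / 2
  }
  stats::setNames(params$mass * mu, grid)
}

# aligned data vector: observed heights on the grid, 0 at unobserved slots
align_heights <- function(heights, alleles, grid) {
  d <- stats::setNames(numeric(length(grid)), grid)
  d[match(as.character(alleles), grid)] <- heights
  d
}

gaussian_loglik <- function(d, mu, params) {
  v <- params$variance_floor + params$variance_scale * mu
  sum(stats::dnorm(d, mean = mu, sd = sqrt(v), log = TRUE))
}

#' Log-likelihood of observed peaks under a genotype hypothesis
#'
#' Multivariate-normal (diagonal) log density of the locus peak heights
#' around the hypothesis' [mean_pattern()]. The allele grid is the union of
#' observed peak positions, hypothesized alleles and their back-stutter
#' positions; data height is 0 at unobserved grid positions, so a hypothesis
#' that predicts unobserved peaks is penalized.
#'
#' @param peaks a [peak_table()] (rows of one locus) or NULL/empty
#' @param genotypes list of allele pairs, one per contributor
#' @param params a [model_params()]
#' @param geom locus geometry
#' @return log-likelihood, or NA (flag) when the locus has no peaks
#' @export
log_likelihood <- function(peaks, genotypes, params, geom) {
  if (is.null(peaks) || nrow(peaks) == 0) return(NA_real_)
  hyp <- unique(unlist(genotypes))
  grid <- build_grid(peaks$allele, hyp, params$stutter_rate)
  mu <- mean_pattern(genotypes, params, geom, grid = grid)
  d <- align_heights(peaks$height_rfu, peaks$allele, grid)
  gaussian_loglik(d, mu, params)
}

#' Joint log posterior of a multi-locus genotype hypothesis
#'
#' Sum over loci of [log_likelihood()] plus the log genotype priors of each
#' contributor's hypothesized pair (defined up to an additive constant
#' shared across hypotheses). A zero prior at a hypothesized pair yields
#' -Inf: the hypothesis is rejected.
#'
#' @param peaks a [peak_table()] (may span loci)
#' @param genotypes named list: locus -> list of pairs (one per contributor)
#' @param params a [model_params()]
#' @param priors named list: locus -> list (per contributor) of
#'   [genotype_dist()] priors, or a single distribution shared by all
#' @param panel an [read_panel()] object
#' @return log posterior (up to a constant)
#' @export
joint_log_posterior <- function(peaks, genotypes, params, priors, panel) {
  total <- 0
  for (loc in names(genotypes)) {
    loc <- toupper(loc)
    rows <- peaks[peaks$locus == loc, , drop = FALSE]
    ll <- log_likelihood(rows, genotypes[[loc]], params,
                         panel_locus(panel, loc))
    if (!is.na(ll)) total <- total + ll
    pri <- priors[[loc]]
    for (k in seq_along(genotypes[[loc]])) {
      pk <- if (inherits(pri, "genotype_dist")) pri else pri[[k]]
      g <- genotypes[[loc]][[k]]
      p <- gd_prob(pk, g[1], g[2])
      total <- total + log(p)
    }
  }
  total
}

#' Method-of-moments variance estimate from heterozygote balance
#'
#' Scans loci that look single-source (exactly two similar-height peaks) and
#' estimates `variance_scale` from the spread of sister-peak differences;
#' falls back to the supplied defaults when fewer than three such loci
#' exist.
#'
#' @param peaks a [peak_table()]
#' @param defaults a [model_params()] supplying fallback values
#' @return list with `variance_scale` and `variance_floor`
#' @export
estimate_variance_params <- function(peaks, defaults = model_params()) {
  diffs <- c(); means <- c()
  for (loc in unique(peaks$locus)) {
    h <- peaks$height_rfu[peaks$locus == loc]
    if (length(h) == 2 && min(h) > 0.6 * max(h)) {
      diffs <- c(diffs, diff(h)); means <- c(means, mean(h))
    }
  }
  if (length(diffs) < 3) {
    return(list(variance_scale = defaults$variance_scale,
                variance_floor = defaults$variance_floor))
  }
  # var(h1 - h2) ~ 2 (floor + scale * mean); solve for scale at fixed floor
  scale <- max((mean(diffs^2) / 2 - defaults$variance_floor) / mean(means),
               0.5)
  list(variance_scale = scale, variance_floor = defaults$variance_floor)
}
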