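# Reliability experiments: specificity against random noncontributors,
# replicate-run precision, and Kolmogorov-Smirnov uniformity checks.

BAN_FLOOR <- -30  # aggregation clamp for strongly exclusionary comparisons

#' Specificity experiment against random noncontributors
#'
#' For each inferred evidence genotype, draws `n_random` random reference
#' genotypes from the theta-corrected population prior, computes the
#' noncontributor weight of evidence (ban), and aggregates tail statistics.
#' Ban values below -30 are clamped at -30 for aggregation (the clamp count
#' is reported).
#'
#' @param evidence list of evidence genotypes: each a named list locus ->
#'   [genotype_dist()] (e.g. [evidence_genotype()] outputs)
#' @param freqs a [freq_table()]
#' @param n_random noncontributor references per evidence genotype
#' @param seed integer seed
#' @param theta co-ancestry coefficient for both priors and sampling
#' @param population population name
#' @return object of class `specificity_report`: n_comparisons, mean / min /
#'   max / sd of the ban values, tail counts at ban > 0, 1, 2, 3,
#'   false-positive rate, clamp count
#' @export
specificity_experiment <- function(evidence, freqs, n_random = 1000, seed = 1,
                                   theta = 0.01, population = NULL) {
  if (n_random < 1) stop_input("n_random must be >= 1")
  if (!is.null(names(evidence)) && inherits(evidence[[1]], "genotype_dist")) {
    evidence <- list(evidence)  # a single evidence genotype was passed
  }
  bans <- with_seed(seed, {
    unlist(lapply(evidence, function(ev) {
      loci <- names(ev)
      priors <- lapply(loci, function(loc) {
        build_prior_distribution(loc, freqs, theta, population)
      })
      names(priors) <- loci
      # log10 LR contribution of every pair at every locus, then n_random
      # random references drawn from the prior
      per_ref <- matrix(0, n_random, length(loci))
      for (j in seq_along(loci)) {
        pr <- priors[[loci[j]]]
        post <- stats::setNames(ev[[loci[j]]]$prob,
                                pair_key(ev[[loci[j]]]$a1, ev[[loci[j]]]$a2))
        idx <- sample.int(nrow(pr), n_random, replace = TRUE, prob = pr$prob)
        po <- post[pair_key(pr$a1, pr$a2)[idx]]
        po[is.na(po)] <- 0
        per_ref[, j] <- log10(po / pr$prob[idx])
      }
      rowSums(per_ref)
    }))
  })
  clamped <- sum(bans < BAN_FLOOR)
  bans <- pmax(bans, BAN_FLOOR)
  tails <- vapply(0:3, function(t) sum(bans > t), 0L)
  structure(list(n_comparisons = length(bans), mean = mean(bans),
                 min = min(bans), max = max(bans), sd = stats::sd(bans),
                 tail_counts = stats::setNames(tails, paste0("ban>", 0:3)),
                 false_positive_rate = tails[1] / length(bans),
                 clamped = clamped, seed = seed),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Noncontributor specificity over", x$n_comparisons, "comparisons\n")
  cat(sprintf("  ban: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              x$mean, x$sd, x$min, x$max))
  cat("  tail counts:", paste(names(x$tail_counts), x$tail_counts,
                              collapse = ", "), "\n")
  cat(sprintf("  false-positive rate (ban > 0): %.4g%%\n",
              100 * x$false_positive_rate))
  invisible(x)
}

#' Within-group standard deviation of replicate-run pairs
#'
#' Precision of the weight of evidence over duplicate runs: each pair
#' contributes the variance of its two values around their own mean
#' (d^2 / 4 for difference d), and the estimator is the square root of the
#' mean within-pair variance. Zero for identical pairs.
#'
#' @param pairs two-column matrix/data.frame of (ban, ban) duplicate values
#' @return object of class `precision_report` with `n_pairs` and `sd`
#' @export
precision_within_group_sd <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs) || ncol(pairs) != 2) {
    stop_input("pairs must be a non-empty two-column structure")
  }
  d <- pairs[, 1] - pairs[, 2]
  structure(list(n_pairs = nrow(pairs), sd = sqrt(mean(d^2 / 4))),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Within-group SD over %d duplicate pairs: %.4f ban\n",
              x$n_pairs, x$sd))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov test against a uniform distribution
#'
#' Tests whether a set of weight-of-evidence values is uniformly distributed
#' over (lower, upper) -- the accuracy signature expected of an unbiased
#' method over an ensemble of randomly composed mixtures. Exact p-values for
#' n <= 50, asymptotic otherwise.
#'
#' @param values numeric vector, n >= 5
#' @param lower,upper range of the uniform reference distribution
#' @return list with `statistic` and `p_value`
#' @export
ks_uniformity <- function(values, lower, upper) {
  if (length(values) < 5) stop_input("need at least 5 values")
  if (!(upper > lower)) stop_input("degenerate range: upper must exceed lower")
  kt <- suppressWarnings(stats::ks.test(values, stats::punif, min = lower,
                                        max = upper,
                                        exact = length(values) <= 50))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' KS uniformity check for mixture weights on (0, 1)
#'
#' @param weights numeric vector of inferred mixture weights
#' @param lower,upper reference range (default the full (0, 1) interval)
#' @return as [ks_uniformity()]
#' @export
weight_uniformity <- function(weights, lower = 0, upper = 1) {
  ks_uniformity(weights, lower, upper)
}
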