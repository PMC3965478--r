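# Population model: allele/genotype spaces, population frequencies,
# theta-corrected genotype priors, random genotype generation.

#' Enumerate unordered allele pairs at a locus
#'
#' Given n alleles there are n(n+1)/2 unordered pairings: n homozygotes and
#' n(n-1)/2 heterozygotes. Pairs are returned canonically sorted (a1 <= a2
#' in allele order) in a deterministic order.
#'
#' @param alleles character vector of distinct allele labels
#' @return data.frame with columns `a1`, `a2`
#' @export
enumerate_pairs <- function(alleles) {
  alleles <- as.character(alleles)
  if (length(alleles) == 0) stop_input("allele list is empty")
  if (anyDuplicated(alleles)) stop_input("duplicate alleles in allele list")
  alleles <- order_alleles(alleles)
  n <- length(alleles)
  i <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  j <- unlist(lapply(seq_len(n), function(k) k:n))
  data.frame(a1 = alleles[i], a2 = alleles[j], stringsAsFactors = FALSE)
}

#' Population allele-frequency table
#'
#' Builds a validated frequency table from per-locus allele frequencies for
#' one or more named populations.
#'
#' @param df data.frame with columns `population`, `locus`, `allele`,
#'   `frequency`
#' @param database_size optional number of individuals behind the table;
#'   sets the minimum frequency 5/(2N) substituted for alleles absent from
#'   the table (fallback 0.001)
#' @return object of class `freq_table`
#' @export
freq_table <- function(df, database_size = NULL) {
  need <- c("population", "locus", "allele", "frequency")
  if (!all(need %in% names(df))) {
    stop_input("frequency table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$population <- as.character(df$population)
  df$locus <- toupper(as.character(df$locus))
  df$allele <- as.character(df$allele)
  df$frequency <- as.numeric(df$frequency)
  if (any(!is.finite(df$frequency)) || any(df$frequency <= 0) ||
      any(df$frequency > 1)) {
    stop_input("allele frequencies must lie in (0, 1]")
  }
  sums <- tapply(df$frequency, paste(df$population, df$locus), sum)
  bad <- names(sums)[sums > 1 + 1e-6]
  if (length(bad)) {
    stop_input("per-locus frequencies sum to > 1 at: ",
               paste(bad, collapse = "; "))
  }
  key <- paste(df$population, df$locus, df$allele)
  if (anyDuplicated(key)) stop_input("duplicate (population, locus, allele) rows")
  structure(df, class = c("freq_table", "data.frame"),
            database_size = database_size)
}

min_allele_frequency <- function(freqs) {
  n <- attr(freqs, "database_size")
  if (is.null(n)) 0.001 else 5 / (2 * n)
}

ft_populations <- function(freqs) unique(freqs$population)

ft_loci <- function(freqs, population = NULL) {
  population <- population %||% ft_populations(freqs)[1]
  unique(freqs$locus[freqs$population == population])
}

#' Per-locus allele frequencies as a named vector
#'
#' Alleles requested via `include` but absent from the table are added at the
#' minimum allele frequency (5/2N or 0.001) with a warning, so unseen
#' reference alleles never get a zero prior.
#'
#' @param freqs a [freq_table()]
#' @param locus locus name
#' @param population population name; defaults to the table's first
#' @param include alleles that must appear in the returned vector
#' @return named numeric vector of frequencies
#' @export
locus_frequencies <- function(freqs, locus, population = NULL, include = NULL) {
  population <- population %||% ft_populations(freqs)[1]
  locus <- toupper(locus)
  sel <- freqs$population == population & freqs$locus == locus
  if (!any(sel)) stop_input("locus ", locus, " absent for population ", population)
  f <- stats::setNames(freqs$frequency[sel], freqs$allele[sel])
  if (!is.null(include)) {
    missing <- setdiff(as.character(include), names(f))
    if (length(missing)) {
      fmin <- min_allele_frequency(freqs)
      warning("allele(s) ", paste(missing, collapse = ", "), " at ", locus,
              " absent from the frequency table; using minimum frequency ",
              signif(fmin, 3), call. = FALSE)
      f[missing] <- fmin
    }
  }
  f[order_alleles(names(f))]
}

# Balding-Nichols genotype sampling weights: the probability of drawing an
# unordered allele pair from a population with co-ancestry theta
# (homozygote p[theta + (1-theta)p], heterozygote 2(1-theta) p_i p_j).
# Sums to 1 exactly when the locus frequencies do; reduces to
# Hardy-Weinberg at theta = 0; every homozygote strictly exceeds its HWE
# value for theta > 0.
bn_pair_weight <- function(p1, p2, homozygote, theta) {
  ifelse(homozygote,
         p1 * (theta + (1 - theta) * p1),
         2 * (1 - theta) * p1 * p2)
}

#' Genotype prior distribution at a locus
#'
#' The prior over all n(n+1)/2 unordered allele pairs, with co-ancestry
#' correction. Pair weights follow the Balding-Nichols genotype sampling
#' distribution (homozygote `p (theta + (1-theta) p)`, heterozygote
#' `2 (1-theta) p_i p_j`), normalized over the locus allele universe so the
#' distribution sums to 1 (a no-op when the locus frequencies themselves sum
#' to 1). At theta = 0 this is exactly Hardy-Weinberg (p^2, 2 p_i p_j); for
#' theta > 0 every homozygote prior strictly exceeds its HWE value.
#'
#' @param locus locus name
#' @param freqs a [freq_table()]
#' @param theta co-ancestry coefficient in \[0, 0.5)
#' @param population population name
#' @param include alleles forced into the universe (minimum-frequency rule)
#' @return a [genotype_dist()]
#' @export
build_prior_distribution <- function(locus, freqs, theta = 0.01,
                                     population = NULL, include = NULL) {
  check_theta(theta)
  f <- locus_frequencies(freqs, locus, population, include = include)
  pairs <- enumerate_pairs(names(f))
  w <- bn_pair_weight(f[pairs$a1], f[pairs$a2], pairs$a1 == pairs$a2, theta)
  genotype_dist(toupper(locus), pairs$a1, pairs$a2, w / sum(w))
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta >= 0.5) {
    stop_input("theta must be a single value in [0, 0.5)")
  }
  invisible(theta)
}

#' Prior probability of one genotype pair
#'
#' @inheritParams build_prior_distribution
#' @param a1,a2 allele labels of the (unordered) pair
#' @return probability in (0, 1]
#' @export
genotype_prior <- function(locus, a1, a2, freqs, theta = 0.01,
                           population = NULL) {
  f <- locus_frequencies(freqs, locus, population)
  pr <- canonical_pair(a1, a2)
  if (!all(pr %in% names(f))) {
    stop_input("allele(s) ", paste(setdiff(pr, names(f)), collapse = ", "),
               " unknown at locus ", locus)
  }
  d <- build_prior_distribution(locus, freqs, theta, population)
  gd_prob(d, pr[1], pr[2])
}

#' Draw a random genotype from the theta-corrected prior
#'
#' Mirrors noncontributor generation for specificity experiments: alleles
#' pairs are selected in proportion to their prevalence in the population
#' database (with co-ancestry correction).
#'
#' @inheritParams build_prior_distribution
#' @param n number of pairs to draw
#' @param seed optional integer seed (RNG state is restored afterwards)
#' @return data.frame with columns `a1`, `a2` (n rows)
#' @export
sample_random_genotype <- function(freqs, locus, theta = 0.01,
                                   population = NULL, n = 1, seed = NULL) {
  d <- build_prior_distribution(locus, freqs, theta, population)
  draw <- function() {
    idx <- sample.int(nrow(d), n, replace = TRUE, prob = d$prob)
    data.frame(a1 = d$a1[idx], a2 = d$a2[idx], stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Genotype probability distribution
#'
#' Probability mass over unordered allele pairs at one locus. Used uniformly
#' for priors, threshold-restricted inclusion posteriors, and MCMC-inferred
#' posteriors.
#'
#' @param locus locus name
#' @param a1,a2 allele labels (recycled, canonicalized)
#' @param prob probabilities, must be >= 0 and sum to 1 within 1e-9
#' @return data.frame of class `genotype_dist` with columns `a1`, `a2`, `prob`
#' @export
genotype_dist <- function(locus, a1, a2, prob) {
  a1 <- as.character(a1); a2 <- as.character(a2)
  if (length(a1) != length(a2) || length(a1) != length(prob)) {
    stop_input("a1, a2, prob must have equal length")
  }
  if (length(prob) == 0) stop_input("genotype distribution needs support")
  swap <- !mapply(allele_le, a1, a2)
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  if (any(prob < -1e-12)) stop_input("negative probability mass")
  prob <- pmax(prob, 0)
  if (abs(sum(prob) - 1) > 1e-9) {
    stop_input("genotype distribution mass sums to ", sum(prob), ", not 1")
  }
  key <- pair_key(a1, a2)
  if (anyDuplicated(key)) stop_input("duplicate pairs in genotype distribution")
  ord <- order(match(a1, order_alleles(unique(c(a1, a2)))),
               match(a2, order_alleles(unique(c(a1, a2)))))
  out <- data.frame(a1 = a1[ord], a2 = a2[ord], prob = prob[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("genotype_dist", "data.frame"),
            locus = toupper(locus))
}

#' Probability of one pair under a genotype distribution
#'
#' @param d a [genotype_dist()]
#' @param a1,a2 allele labels (order-free)
#' @return probability (0 when the pair is outside the support)
#' @export
gd_prob <- function(d, a1, a2) {
  pr <- canonical_pair(a1, a2)
  hit <- d$a1 == pr[1] & d$a2 == pr[2]
  if (any(hit)) d$prob[hit][1] else 0
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat("Genotype distribution at", attr(x, "locus"), "(",
      nrow(x), "pairs )\n")
  top <- x[order(-x$prob), , drop = FALSE]
  print.data.frame(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}
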