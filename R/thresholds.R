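# Manual comparator methods: analytical-threshold allele calling, CPI
# inclusion statistics, and mCPI stochastic-threshold locus filtering.

#' Threshold configuration
#'
#' Defaults are the modelled laboratory's values: analytical thresholds of
#' 73 RFU (blue), 84 (green), 75 (yellow), 52 (red); stochastic thresholds
#' of 210 RFU at 2 s injection, 320 at 5 s, 460 at 10 s. Comparisons use >=
#' (a peak exactly at threshold is called); set `strict = TRUE` for strict
#' inequality.
#'
#' @param analytical_by_dye named RFU vector, one entry per dye
#' @param stochastic_by_injection named RFU vector keyed by injection seconds
#' @param strict use `>` instead of `>=` at the thresholds
#' @return object of class `threshold_config`
#' @export
threshold_config <- function(analytical_by_dye = c(blue = 73, green = 84,
                                                   yellow = 75, red = 52),
                             stochastic_by_injection = c(`2` = 210, `5` = 320,
                                                         `10` = 460),
                             strict = FALSE) {
  if (any(analytical_by_dye <= 0) || any(stochastic_by_injection <= 0)) {
    stop_input("thresholds must be > 0")
  }
  if (min(stochastic_by_injection) < max(analytical_by_dye)) {
    stop_input("stochastic thresholds must not fall below analytical ones")
  }
  structure(list(analytical_by_dye = analytical_by_dye,
                 stochastic_by_injection = stochastic_by_injection,
                 strict = strict),
            class = "threshold_config")
}

#' Call alleles above the analytical threshold
#'
#' Reduces quantitative peaks to all-or-none allele events: a peak is called
#' when its height reaches the analytical threshold of its dye, and marked
#' `above_stochastic` when it also reaches the stochastic threshold of its
#' injection time.
#'
#' @param peaks a [peak_table()]
#' @param cfg a [threshold_config()]
#' @return data.frame of class `allele_calls`: `locus`, `allele`,
#'   `height_rfu`, `above_stochastic`
#' @export
call_alleles <- function(peaks, cfg = threshold_config()) {
  at <- cfg$analytical_by_dye[peaks$dye]
  if (anyNA(at)) {
    stop_input("unknown dye(s): ",
               paste(unique(peaks$dye[is.na(at)]), collapse = ", "))
  }
  st <- cfg$stochastic_by_injection[as.character(peaks$injection_s)]
  if (anyNA(st)) {
    stop_input("no stochastic threshold for injection time(s): ",
               paste(unique(peaks$injection_s[is.na(st)]), collapse = ", "))
  }
  called <- if (cfg$strict) peaks$height_rfu > at else peaks$height_rfu >= at
  out <- data.frame(locus = peaks$locus[called], allele = peaks$allele[called],
                    height_rfu = peaks$height_rfu[called],
                    above_stochastic = if (cfg$strict) {
                      peaks$height_rfu[called] > st[called]
                    } else {
                      peaks$height_rfu[called] >= st[called]
                    },
                    stringsAsFactors = FALSE)
  structure(out, class = c("allele_calls", "data.frame"))
}

calls_at_locus <- function(calls, locus) {
  calls[calls$locus == toupper(locus), , drop = FALSE]
}

#' Threshold-restricted inclusion posterior
#'
#' The inclusion likelihood assigns 1 to every allele pair formed from the
#' called alleles (or, with `stochastic_only`, from the calls above the
#' stochastic threshold) and 0 otherwise; multiplying the prior by this 0/1
#' likelihood and renormalizing gives the inclusion genotype distribution.
#'
#' @param calls an [call_alleles()] result restricted to one locus (or not;
#'   the `locus` of `prior` selects rows)
#' @param prior the locus [genotype_dist()] prior
#' @param stochastic_only restrict to calls above the stochastic threshold
#' @return a [genotype_dist()], or NULL when the allowed call set is empty
#'   (locus inconclusive)
#' @export
inclusion_posterior <- function(calls, prior, stochastic_only = FALSE) {
  lc <- calls_at_locus(calls, attr(prior, "locus"))
  allowed <- if (stochastic_only) lc$allele[lc$above_stochastic] else lc$allele
  if (!length(allowed)) return(NULL)
  keep <- prior$a1 %in% allowed & prior$a2 %in% allowed
  mass <- sum(prior$prob[keep])
  if (mass == 0) return(NULL)
  genotype_dist(attr(prior, "locus"), prior$a1[keep], prior$a2[keep],
                prior$prob[keep] / mass)
}

#' CPI inclusion probability at a locus
#'
#' The probability that a random person is not excluded: the squared sum of
#' the called-allele frequencies. With theta > 0, computed instead as the
#' summed theta-corrected prior mass of the included pairs (identical at
#' theta = 0).
#'
#' @param calls an [call_alleles()] result
#' @param locus locus name
#' @param freqs a [freq_table()]
#' @param theta co-ancestry coefficient (comparator default 0, matching the
#'   usual manual arithmetic)
#' @param population population name
#' @return inclusion probability in (0, 1]
#' @export
cpi_locus_probability <- function(calls, locus, freqs, theta = 0,
                                  population = NULL) {
  lc <- calls_at_locus(calls, locus)
  if (!nrow(lc)) stop_input("no called alleles at ", locus)
  f <- locus_frequencies(freqs, locus, population, include = lc$allele)
  if (theta == 0) {
    p <- min(sum(f[lc$allele]), 1)
    return(p^2)
  }
  prior <- build_prior_distribution(locus, freqs, theta, population,
                                    include = lc$allele)
  keep <- prior$a1 %in% lc$allele & prior$a2 %in% lc$allele
  min(sum(prior$prob[keep]), 1)
}

#' Is a locus usable under the mCPI stochastic-threshold rule?
#'
#' TRUE only when every called allele also reaches the stochastic threshold;
#' a locus with any intermediate-height call (or no calls at all) is dropped
#' from the mCPI statistic.
#'
#' @param calls an [call_alleles()] result
#' @param locus locus name
#' @return logical flag
#' @export
mcpi_locus_usable <- function(calls, locus) {
  lc <- calls_at_locus(calls, locus)
  nrow(lc) > 0 && all(lc$above_stochastic)
}

#' CPI / mCPI match against a reference profile
#'
#' Mechanical threshold-method rules: at each locus with calls, the
#' reference is excluded if any of its alleles is uncalled; otherwise the
#' locus LR is the reciprocal of the inclusion probability. mCPI
#' additionally drops loci that fail [mcpi_locus_usable()]. The combined LR
#' is the product over used loci; with no usable locus the result is
#' inconclusive, with no statistic.
#'
#' @param calls an [call_alleles()] result for the evidence sample
#' @param reference a [contributor_profile()]
#' @param freqs a [freq_table()]
#' @param method `"cpi"` or `"mcpi"`
#' @param theta co-ancestry coefficient (default 0 for the comparators)
#' @param population population name
#' @param sample sample label carried into the result
#' @return a `match_result`
#' @export
inclusion_match <- function(calls, reference, freqs, method = c("cpi", "mcpi"),
                            theta = 0, population = NULL, sample = "evidence") {
  method <- match.arg(method)
  loci <- intersect(unique(calls$locus), names(reference$genotypes))
  per <- data.frame(locus = loci, lr = NA_real_, used = FALSE,
                    note = "", stringsAsFactors = FALSE)
  excluded <- FALSE
  for (i in seq_along(loci)) {
    loc <- loci[i]
    lc <- calls_at_locus(calls, loc)
    if (!nrow(lc)) { per$note[i] <- "no calls"; next }
    ref <- reference$genotypes[[loc]]
    if (!all(ref %in% lc$allele)) {
      per$note[i] <- "reference allele not called: exclusion"
      excluded <- TRUE
      next
    }
    if (method == "mcpi" && !mcpi_locus_usable(calls, loc)) {
      per$note[i] <- "below stochastic threshold: locus dropped"
      next
    }
    per$lr[i] <- 1 / cpi_locus_probability(calls, loc, freqs, theta, population)
    per$used[i] <- TRUE
  }
  used <- per$used
  if (excluded) {
    combined <- NA_real_; ban <- NA_real_; class_ <- "exclude"
  } else if (!any(used)) {
    combined <- NA_real_; ban <- NA_real_; class_ <- "inconclusive"
  } else {
    cb <- combine_loci(stats::setNames(per$lr[used], per$locus[used]))
    combined <- cb$lr; ban <- cb$ban
    class_ <- "include"
  }
  match_result(sample = sample, reference = reference$sample_name,
               population = population %||% ft_populations(freqs)[1],
               method = toupper(method), per_locus = per,
               combined_lr = combined, log10_lr = ban,
               classification = class_)
}
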