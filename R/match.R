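# Likelihood-ratio match statistics: per-locus posterior/prior ratios,
# multi-locus combination, population minimization, classification.

#' Match result container
#'
#' @param sample evidence sample label
#' @param reference reference sample label
#' @param population population label
#' @param method method label ("GENOTYPE", "CPI", "MCPI", ...)
#' @param per_locus data.frame with columns `locus`, `lr`, `used`, `note`
#' @param combined_lr product of per-locus LRs over used loci (NA when no
#'   statistic exists)
#' @param log10_lr base-10 log of the combined LR, in ban
#' @param classification "include", "inconclusive" or "exclude"
#' @return object of class `match_result`
#' @export
match_result <- function(sample, reference, population, method, per_locus,
                         combined_lr, log10_lr, classification) {
  structure(list(sample = sample, reference = reference,
                 population = population, method = method,
                 per_locus = per_locus, combined_lr = combined_lr,
                 log10_lr = log10_lr, classification = classification),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("%s match: %s vs %s (population %s)\n", x$method, x$sample,
              x$reference, x$population))
  if (is.na(x$combined_lr)) {
    cat("No match statistic (", x$classification, ")\n", sep = "")
  } else {
    cat(sprintf("Combined LR %.4g (%.2f ban): %s\n", x$combined_lr,
                x$log10_lr, x$classification))
  }
  invisible(x)
}

#' Per-locus likelihood ratio from genotype distributions
#'
#' The LR is the ratio of posterior (after having seen the evidence) to
#' prior (population) genotype probability, evaluated at the reference's
#' allele pair. Equals 1 when posterior = prior (no information) and 0 when
#' the posterior excludes the reference pair.
#'
#' @param posterior,prior [genotype_dist()] objects at one locus
#' @param ref reference allele pair `c(a1, a2)`
#' @return LR >= 0
#' @export
locus_lr <- function(posterior, prior, ref) {
  pr <- gd_prob(prior, ref[1], ref[2])
  if (pr <= 0) stop_input("reference pair has zero prior: LR undefined")
  gd_prob(posterior, ref[1], ref[2]) / pr
}

#' Combine per-locus LRs across independent loci
#'
#' Multiplies the per-locus values and reports the base-10 log (ban). A zero
#' locus LR gives combined 0 and -Inf ban (exclusionary support).
#'
#' @param locus_lrs named numeric vector of per-locus LRs
#' @return list with `lr` and `ban`
#' @export
combine_loci <- function(locus_lrs) {
  if (!length(locus_lrs)) stop_input("no per-locus LRs to combine")
  lr <- prod(locus_lrs)
  list(lr = lr, ban = log10(lr))
}

#' Classify a weight of evidence
#'
#' A positive log(LR) supports a match, a negative one does not, and values
#' near zero are inconclusive; "near zero" is the configurable
#' `inconclusive_band` (default 0.5 ban).
#'
#' @param ban log10(LR)
#' @param inconclusive_band half-width of the inconclusive zone, >= 0
#' @return "include", "inconclusive" or "exclude"
#' @export
classify_log_lr <- function(ban, inconclusive_band = 0.5) {
  if (inconclusive_band < 0) stop_input("band must be >= 0")
  if (is.na(ban)) return("inconclusive")
  if (ban > inconclusive_band) "include"
  else if (ban < -inconclusive_band) "exclude"
  else "inconclusive"
}

#' Genotype-model match statistic for an inferred evidence genotype
#'
#' Compares one contributor's posterior genotype distribution against a
#' reference profile, relative to a population: per-locus LR =
#' posterior/prior at the reference pair, combined by [combine_loci()].
#'
#' @param result an [infer()] result (or a named list locus ->
#'   [genotype_dist()] via `evidence =`)
#' @param reference a [contributor_profile()]
#' @param contributor which contributor slot to compare
#' @param inconclusive_band classification band in ban
#' @param evidence optional explicit evidence genotype (overrides `result`)
#' @param priors optional named list locus -> prior [genotype_dist()]
#'   (defaults to the priors stored in `result`)
#' @param population population label for the report
#' @return a `match_result` with method "GENOTYPE"
#' @export
genotype_match <- function(result = NULL, reference, contributor = 1,
                           inconclusive_band = 0.5, evidence = NULL,
                           priors = NULL, population = NULL) {
  evidence <- evidence %||% evidence_genotype(result, contributor)
  priors <- priors %||% result$priors
  population <- population %||%
    (result$settings$population %||% "population")
  loci <- intersect(names(evidence), names(reference$genotypes))
  if (!length(loci)) stop_input("no shared loci between evidence and reference")
  lrs <- vapply(loci, function(loc) {
    locus_lr(evidence[[loc]], priors[[loc]], reference$genotypes[[loc]])
  }, 0)
  cb <- combine_loci(lrs)
  match_result(
    sample = if (!is.null(result)) "evidence" else "evidence",
    reference = reference$sample_name, population = population,
    method = "GENOTYPE",
    per_locus = data.frame(locus = loci, lr = unname(lrs), used = TRUE,
                           note = "", stringsAsFactors = FALSE),
    combined_lr = cb$lr, log10_lr = cb$ban,
    classification = classify_log_lr(cb$ban, inconclusive_band))
}

#' Conservative minimum over population-specific results
#'
#' Reporting convention: when several population databases are used, take
#' the smallest of the match statistics. Ties break by population name
#' order.
#'
#' @param results list of `match_result`s for the same sample/reference
#' @return the `match_result` with the smallest combined LR
#' @export
min_over_populations <- function(results) {
  if (inherits(results, "match_result")) return(results)
  refs <- vapply(results, `[[`, "", "reference")
  if (length(unique(refs)) != 1) stop_input("mixed references in results")
  lrs <- vapply(results, function(r) r$combined_lr %||% NA_real_, 0)
  pops <- vapply(results, `[[`, "", "population")
  ord <- order(lrs, pops)
  results[[ord[1]]]
}

#' Plain-language match statement
#'
#' @param result a `match_result`
#' @return one-sentence character rendering of the statistic
#' @export
format_match_statement <- function(result) {
  if (is.na(result$combined_lr)) {
    return(sprintf("The comparison between the evidence and %s is %s.",
                   result$reference, result$classification))
  }
  sprintf(paste("A match between the evidence and %s is %s times more",
                "probable than coincidence."),
          result$reference, signif(result$combined_lr, 3))
}
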