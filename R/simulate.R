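# EPG simulator: synthetic quantitative STR peak data with known ground
# truth (mixture weights, template mass, back-stutter, size-dependent
# degradation, lognormal multiplicative peak-height noise).

#' Contributor profile
#'
#' @param sample_name sample label
#' @param genotypes named list: locus -> c(a1, a2)
#' @return object of class `contributor_profile`
#' @export
contributor_profile <- function(sample_name, genotypes) {
  if (!length(genotypes) || is.null(names(genotypes))) {
    stop_input("genotypes must be a named (by locus) list of allele pairs")
  }
  genotypes <- lapply(genotypes, function(g) {
    if (length(g) != 2) stop_input("each genotype must be a pair of alleles")
    canonical_pair(g[1], g[2])
  })
  names(genotypes) <- toupper(names(genotypes))
  structure(list(sample_name = sample_name, genotypes = genotypes),
            class = "contributor_profile")
}

#' Draw a random contributor profile from population priors
#'
#' @param freqs a [freq_table()]
#' @param panel an [read_panel()] object
#' @param sample_name label for the profile
#' @param theta co-ancestry coefficient for the genotype prior
#' @param population population name
#' @return a [contributor_profile()]
#' @export
random_profile <- function(freqs, panel, sample_name = "random",
                           theta = 0.01, population = NULL) {
  gts <- lapply(panel_loci(panel), function(loc) {
    g <- sample_random_genotype(freqs, loc, theta, population)
    c(g$a1[1], g$a2[1])
  })
  names(gts) <- panel_loci(panel)
  contributor_profile(sample_name, gts)
}

#' Mixture specification for the EPG simulator
#'
#' Defaults define the simulated study conditions: a 3000 RFU combined
#' allelic intensity per locus, 5 percent back-stutter, no degradation,
#' 10 percent coefficient of variation of peak height, 5 s injection.
#'
#' @param contributors list of [contributor_profile()]
#' @param weights mixture weights, > 0, summing to 1 within 1e-9
#' @param total_mass combined allelic fluorescence (RFU) per locus; scalar
#'   or named per-locus vector
#' @param stutter_rate back-stutter fraction in \[0, 0.3)
#' @param degradation_rate exponential decay per 100 bp of fragment size
#' @param cv coefficient of variation of peak height (lognormal noise)
#' @param injection_s capillary injection time, one of 2, 5, 10 seconds
#' @return object of class `mixture_spec`
#' @export
mixture_spec <- function(contributors, weights, total_mass = 3000,
                         stutter_rate = 0.05, degradation_rate = 0,
                         cv = 0.1, injection_s = 5) {
  if (inherits(contributors, "contributor_profile")) {
    contributors <- list(contributors)
  }
  if (length(contributors) != length(weights)) {
    stop_input("contributor count must equal weight count")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_input("weights must be > 0 and sum to 1")
  }
  if (stutter_rate < 0 || stutter_rate >= 0.3) {
    stop_input("stutter_rate must lie in [0, 0.3)")
  }
  if (degradation_rate < 0) stop_input("degradation_rate must be >= 0")
  if (cv < 0) stop_input("cv must be >= 0")
  if (!injection_s %in% c(2, 5, 10)) {
    stop_input("injection_s must be one of 2, 5, 10")
  }
  structure(list(contributors = contributors, weights = weights,
                 total_mass = total_mass, stutter_rate = stutter_rate,
                 degradation_rate = degradation_rate, cv = cv,
                 injection_s = injection_s),
            class = "mixture_spec")
}

locus_mass <- function(spec, locus) {
  m <- spec$total_mass
  if (!is.null(names(m))) {
    if (!toupper(locus) %in% toupper(names(m))) {
      stop_input("no total_mass entry for locus ", locus)
    }
    unname(m[toupper(names(m)) == toupper(locus)])
  } else m
}

# value of named-vector element, 0 when absent
vec_at <- function(x, name) {
  v <- unname(x[name])
  if (length(v) == 0 || is.na(v)) 0 else v
}

# Noise-free expected peak heights for one locus; returns named vector over
# allele labels. Mass-conserving stutter: a parent of height h keeps
# (1 - s) h and deposits s h one repeat shorter.
expected_locus_heights <- function(spec, locus, geom) {
  m <- locus_mass(spec, locus)
  dose <- numeric(0)
  for (k in seq_along(spec$contributors)) {
    g <- spec$contributors[[k]]$genotypes[[toupper(locus)]]
    if (is.null(g)) stop_input("contributor ", k, " has no genotype at ", locus)
    for (a in g) dose[a] <- vec_at(dose, a) + spec$weights[k] / 2
  }
  dose <- dose[order_alleles(names(dose))]
  h <- m * dose * exp(-spec$degradation_rate *
                        allele_size_bp(geom, names(dose)) / 100)
  if (spec$stutter_rate > 0) {
    st <- stutter_allele(names(h))
    out <- stats::setNames(h * (1 - spec$stutter_rate), names(h))
    for (i in seq_along(h)) {
      out[st[i]] <- vec_at(out, st[i]) + spec$stutter_rate * h[i]
    }
    h <- out[order_alleles(names(out))]
  }
  h
}

#' Simulate peaks at one locus
#'
#' Expected height of allele a is
#' `total_mass * sum_k w_k * dose_k(a)/2 * exp(-degradation_rate * size/100)`,
#' with a `stutter_rate` fraction moved one repeat shorter, then lognormal
#' multiplicative noise with the stated cv (cv = 0 gives the exact mean
#' pattern).
#'
#' @param spec a [mixture_spec()]
#' @param locus locus name
#' @param panel an [read_panel()] object
#' @param seed optional integer seed
#' @param sample_name sample label for the rows
#' @return a [peak_table()] (rows for one locus)
#' @export
simulate_locus_peaks <- function(spec, locus, panel, seed = NULL,
                                 sample_name = "sim") {
  geom <- panel_locus(panel, locus)
  run <- function() simulate_locus_peaks_(spec, locus, geom, sample_name)
  if (is.null(seed)) run() else with_seed(seed, run())
}

simulate_locus_peaks_ <- function(spec, locus, geom, sample_name) {
  mu <- expected_locus_heights(spec, locus, geom)
  h <- mu
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    pos <- mu > 0
    h[pos] <- stats::rlnorm(sum(pos), meanlog = log(mu[pos]) - sdlog^2 / 2,
                            sdlog = sdlog)
  }
  peak_table(data.frame(
    sample = sample_name, locus = toupper(locus), dye = geom$dye,
    allele = names(h), size_bp = allele_size_bp(geom, names(h)),
    height_rfu = unname(h), injection_s = spec$injection_s,
    stringsAsFactors = FALSE))
}

#' Simulate a whole multi-locus profile
#'
#' One seed governs the whole profile reproducibly. The detection floor
#' (default 10 RFU, the baseline noise level below which peaks are not
#' used) is applied at the end; set `detection_floor = 0` for raw output.
#'
#' @inheritParams simulate_locus_peaks
#' @param loci loci to simulate (default: all panel loci)
#' @param detection_floor RFU floor applied via [apply_detection_floor()]
#' @return a [peak_table()]
#' @export
simulate_profile <- function(spec, panel, loci = panel_loci(panel),
                             seed = NULL, sample_name = "sim",
                             detection_floor = 10) {
  if (!length(loci)) stop_input("empty locus list")
  run <- function() {
    rows <- lapply(loci, function(loc) {
      simulate_locus_peaks_(spec, loc, panel_locus(panel, loc), sample_name)
    })
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- peak_table(out)
  apply_detection_floor(out, detection_floor)
}

#' Remove peaks below a detection floor
#'
#' Peaks below the baseline noise level (10 RFU in the modelled workflow)
#' are not used. Loci whose every peak falls below the floor are flagged in
#' the `dropped_loci` attribute.
#'
#' @param peaks a [peak_table()]
#' @param floor_rfu RFU floor, >= 0; rows with height < floor are removed
#' @return filtered [peak_table()]
#' @export
apply_detection_floor <- function(peaks, floor_rfu) {
  if (floor_rfu < 0) stop_input("floor must be >= 0")
  keep <- peaks$height_rfu >= floor_rfu
  out <- peaks[keep, , drop = FALSE]
  dropped <- setdiff(unique(peaks$locus), unique(out$locus))
  structure(peak_table(as.data.frame(out)), dropped_loci = dropped)
}
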