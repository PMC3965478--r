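# Shared fixtures, all built in code.

pp_panel <- read_panel()

# one-population frequency table over explicit alleles at one locus
toy_freqs <- function(alleles, probs, locus = "TPOX", population = "POP1",
                      database_size = 250) {
  freq_table(data.frame(population = population, locus = locus,
                        allele = as.character(alleles), frequency = probs,
                        stringsAsFactors = FALSE),
             database_size = database_size)
}

# synthetic three-population panel frequencies (fixed generator seed)
pp_freqs <- synthetic_frequencies(pp_panel)

# a reproducible two-person mixture with known ground truth
make_mixture <- function(seed, w_major = 0.7, cv = 0.1, freqs = pp_freqs,
                         panel = pp_panel) {
  profiles <- with_test_seed(seed, list(
    major = random_profile(freqs, panel, "major"),
    minor = random_profile(freqs, panel, "minor")))
  spec <- mixture_spec(list(profiles$major, profiles$minor),
                       c(w_major, 1 - w_major), cv = cv)
  peaks <- simulate_profile(spec, panel, seed = seed + 1000L)
  list(major = profiles$major, minor = profiles$minor, spec = spec,
       peaks = peaks, w_major = w_major)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

quiet_infer <- function(...) suppressWarnings(infer(...))

mode_pair <- function(d) {
  i <- which.max(d$prob)
  c(d$a1[i], d$a2[i])
}
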