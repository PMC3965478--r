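Package: pgmix
Title: Probabilistic Genotyping of STR DNA Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative interpretation of short tandem repeat (STR) DNA
    mixture evidence. Simulates electropherogram peak data with known ground
    truth (stutter, degradation, heteroscedastic peak-height noise), infers
    per-contributor genotype posterior distributions by Markov chain Monte
    Carlo under a multivariate-normal peak-pattern likelihood, computes
    likelihood-ratio match statistics with co-ancestry correction, and
    implements the two threshold-based manual comparators: the combined
    probability of inclusion (CPI) and its stochastic-threshold modification
    (mCPI). Includes reliability experiments (specificity against random
    noncontributors, replicate-run precision, Kolmogorov-Smirnov uniformity
    checks) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
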