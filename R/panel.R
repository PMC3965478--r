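# STR panel description: loci, dye channels, repeat unit lengths, allele
# ranges and fragment-size offsets. A PowerPlex-16-style 15-locus panel is
# bundled as plain JSON under extdata.

#' Load an STR panel description
#'
#' A panel maps each locus to its dye channel, repeat unit length (bp),
#' allele label list and fragment-size offset; fragment size is synthesized
#' as `offset_bp + repeat * repeat_bp`.
#'
#' @param path path to a panel JSON/YAML file; defaults to the bundled
#'   15-locus PowerPlex-16-like panel
#' @return object of class `str_panel`
#' @export
read_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "powerplex16_like_panel.json",
                                package = "pgmix", mustWork = TRUE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  loci <- lapply(raw$loci, function(l) {
    list(locus = toupper(l$locus), dye = l$dye,
         repeat_bp = as.numeric(l$repeat_bp),
         offset_bp = as.numeric(l$offset_bp),
         alleles = order_alleles(vapply(l$alleles, as.character, "")))
  })
  names(loci) <- vapply(loci, `[[`, "", "locus")
  structure(list(name = raw$name %||% basename(path), loci = loci),
            class = "str_panel")
}

#' @export
print.str_panel <- function(x, ...) {
  cat("STR panel:", x$name, "-", length(x$loci), "loci\n")
  for (l in x$loci) {
    cat(sprintf("  %-8s %-7s %d bp repeat, alleles %s..%s\n", l$locus, l$dye,
                l$repeat_bp, l$alleles[1], l$alleles[length(l$alleles)]))
  }
  invisible(x)
}

panel_loci <- function(panel) names(panel$loci)

panel_locus <- function(panel, locus) {
  locus <- toupper(locus)
  if (!locus %in% names(panel$loci)) stop_input("locus ", locus, " not in panel")
  panel$loci[[locus]]
}

# fragment size (bp) of an allele at a locus
allele_size_bp <- function(geom, alleles) {
  geom$offset_bp + allele_numeric(alleles) * geom$repeat_bp
}

# back-stutter label: one repeat unit shorter
stutter_allele <- function(alleles) {
  format_allele(allele_numeric(alleles) - 1)
}

#' Synthetic population allele frequencies for a panel
#'
#' Generates seeded per-locus allele frequencies for one or more synthetic
#' populations. Frequencies follow a Dirichlet draw whose concentration is
#' shaped unimodally along the allele ladder, mimicking the common-allele
#' structure of real STR databases. This is a synthetic stand-in for
#' laboratory population databases, which are not distributable.
#'
#' @param panel an [read_panel()] object
#' @param populations character vector of population labels
#' @param seed integer seed
#' @param database_size nominal database size (sets the minimum frequency)
#' @return a [freq_table()]
#' @export
synthetic_frequencies <- function(panel, populations = c("POP1", "POP2", "POP3"),
                                  seed = 17, database_size = 250) {
  rows <- with_seed(seed, {
    out <- list()
    for (pop in populations) {
      for (l in panel$loci) {
        n <- length(l$alleles)
        x <- seq_len(n)
        shape <- 8 * stats::dnorm(x, mean = (n + 1) / 2 +
                                    stats::runif(1, -n / 6, n / 6),
                                  sd = n / 4)
        shape <- pmax(shape * n / sum(shape), 0.15)
        g <- stats::rgamma(n, shape = shape, rate = 1)
        f <- g / sum(g)
        # keep every allele representable at >= 1/(2 * database_size)
        fmin <- 1 / (2 * database_size)
        f <- pmax(f, fmin)
        f <- f / sum(f)
        f <- round(f, 4)
        f[which.max(f)] <- f[which.max(f)] + (1 - sum(f))
        out[[length(out) + 1L]] <- data.frame(
          population = pop, locus = l$locus, allele = l$alleles,
          frequency = f, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  freq_table(rows, database_size = database_size)
}
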