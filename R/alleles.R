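#' @keywords internal
"_PACKAGE"

# Allele labels are opaque strings ("9", "9.3", ...). They are ordered
# numerically when every label parses as a number, lexically otherwise,
# so microvariant alleles sort where an analyst expects them.

allele_numeric <- function(labels) {
  suppressWarnings(as.numeric(labels))
}

#' Order allele labels
#'
#' Returns the labels sorted in canonical order: numeric order when all
#' labels parse as numbers (so "9.3" falls between "9" and "10"), lexical
#' order otherwise.
#'
#' @param labels character vector of allele labels
#' @return character vector, sorted
#' @export
order_alleles <- function(labels) {
  labels <- as.character(labels)
  num <- allele_numeric(labels)
  if (!anyNA(num)) labels[order(num)] else sort(labels)
}

# TRUE if a sorts at or before b in canonical allele order
allele_le <- function(a, b) {
  na <- allele_numeric(a); nb <- allele_numeric(b)
  if (!is.na(na) && !is.na(nb)) na <= nb else a <= b
}

# canonicalize an unordered pair -> c(a1, a2) with a1 <= a2
canonical_pair <- function(a1, a2) {
  a1 <- as.character(a1); a2 <- as.character(a2)
  if (allele_le(a1, a2)) c(a1, a2) else c(a2, a1)
}

pair_key <- function(a1, a2) paste(a1, a2, sep = "/")

# format a numeric repeat value back to an allele label ("8", "8.3");
# rounding absorbs floating-point fuzz from repeat arithmetic
format_allele <- function(x) {
  s <- format(round(x, 6), scientific = FALSE, trim = TRUE)
  sub("\\.0+$", "", s)
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
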