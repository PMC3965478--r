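# Readers/writers: peak tables (CSV/JSON), frequency tables, reference
# profiles, match reports, run configuration.

PEAK_COLS <- c("sample", "locus", "dye", "allele", "size_bp", "height_rfu",
               "injection_s")

#' Quantitative EPG peak table
#'
#' Per-locus labelled peaks with fragment size (bp), height (RFU), dye
#' channel and injection time: the quantitative data vector the genotype
#' model explains.
#'
#' @param df data.frame with columns `sample`, `locus`, `dye`, `allele`,
#'   `size_bp`, `height_rfu`, `injection_s`
#' @return data.frame of class `peak_table`
#' @export
peak_table <- function(df) {
  if (!all(PEAK_COLS %in% names(df))) {
    stop_input("peak table needs columns: ", paste(PEAK_COLS, collapse = ", "))
  }
  df <- as.data.frame(df)[PEAK_COLS]
  df$sample <- as.character(df$sample)
  df$locus <- toupper(as.character(df$locus))
  df$dye <- as.character(df$dye)
  df$allele <- as.character(df$allele)
  df$size_bp <- as.numeric(df$size_bp)
  df$height_rfu <- as.numeric(df$height_rfu)
  df$injection_s <- as.numeric(df$injection_s)
  bad <- which(!is.finite(df$height_rfu) | df$height_rfu < 0)
  if (length(bad)) {
    stop_input("negative or missing peak height at row(s) ",
               paste(bad, collapse = ", "))
  }
  key <- paste(df$sample, df$locus, df$allele)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_input("duplicate (locus, allele) peak at row(s) ",
               paste(dup, collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("peak_table", "data.frame"))
}

#' Read a peak table from CSV or JSON
#'
#' @param path file path; format chosen by extension (.csv or .json)
#' @return a [peak_table()]
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  peak_table(df)
}

#' Write a peak table to CSV or JSON
#'
#' @param peaks a [peak_table()]
#' @param path output path (.csv or .json)
#' @export
write_peak_table <- function(peaks, path) {
  df <- as.data.frame(peaks)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a population frequency CSV
#'
#' Expected columns: `population,locus,allele,frequency` (UTF-8, header
#' required).
#'
#' @param path file path
#' @param database_size optional database size behind the table
#' @return a [freq_table()]
#' @export
read_frequencies <- function(path, database_size = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  freq_table(utils::read.csv(path, stringsAsFactors = FALSE),
             database_size = database_size)
}

#' @rdname read_frequencies
#' @param freqs a [freq_table()]
#' @export
write_frequencies <- function(freqs, path) {
  utils::write.csv(as.data.frame(freqs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference genotype profiles
#'
#' Expected columns: `sample,locus,allele1,allele2`.
#'
#' @param path CSV file path
#' @return list of [contributor_profile()]
#' @export
read_references <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop_input("reference CSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$sample), function(d) {
    gts <- lapply(seq_len(nrow(d)), function(i) {
      c(as.character(d$allele1[i]), as.character(d$allele2[i]))
    })
    names(gts) <- d$locus
    contributor_profile(d$sample[1], gts)
  })
}

#' @rdname read_references
#' @param profiles list of [contributor_profile()] (or a single one)
#' @export
write_references <- function(profiles, path) {
  if (inherits(profiles, "contributor_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = p$sample_name, locus = names(p$genotypes),
               allele1 = vapply(p$genotypes, `[`, "", 1),
               allele2 = vapply(p$genotypes, `[`, "", 2),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# rolling polynomial hash of a character scalar, as 8 hex digits; stamps
# outputs with a configuration fingerprint without external dependencies
config_hash <- function(x) {
  if (!is.character(x)) {
    x <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Write a match result as a JSON report
#'
#' The report embeds the method, per-locus LR table, combined LR and ban,
#' classification, the plain-language match statement, and provenance
#' (seed, settings hash, package version).
#'
#' @param result a `match_result`
#' @param path output JSON path
#' @param seed seed recorded in the provenance block
#' @export
write_match_report <- function(result, path, seed = NULL) {
  rep <- unclass(result)
  rep$statement <- format_match_statement(result)
  rep$provenance <- list(
    package = "pgmix",
    version = as.character(utils::packageVersion("pgmix")),
    seed = seed,
    config_hash = config_hash(rep[setdiff(names(rep), "provenance")]))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
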