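#' Write a tibble as a TSV report
#'
#' All tabular outputs of the package share one dialect: tab-separated,
#' UTF-8, LF line endings, `"."` for missing values, with optional leading
#' `#` comment lines recording provenance (most importantly which filters
#' were applied). List-columns are collapsed with the given separator.
#' Identical input always produces byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comments Character vector of comment lines (written as `# ...`).
#' @param list_sep Separator for list-column cells (default `";"`).
#' @return `path`, invisibly.
#' @export
write_tegc_tsv <- function(x, path, comments = character(), list_sep = ";") {
  flat <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ purrr::map_chr(.x, function(v) {
      if (length(v) == 0) NA_character_ else paste(format(v, trim = TRUE,
                                                          digits = 15),
                                                  collapse = list_sep)
    })
  ))
  body <- readr::format_tsv(flat, na = ".")
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con, sep = "\n", useBytes = TRUE)
  }
  writeLines(sub("\n$", "", body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a species metadata table
#'
#' Serialises a species tibble back to the TSV dialect read by
#' [load_species_table()]: C-values `;`-separated, lineage flags
#' `|`-separated, `.` for missing.
#'
#' @param records Species tibble.
#' @param path Output path.
#' @param comments Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path, comments = character()) {
  out <- records
  if ("lineage_flags" %in% names(out) && is.list(out$lineage_flags)) {
    out$lineage_flags <- purrr::map_chr(out$lineage_flags, function(v) {
      if (length(v) == 0) NA_character_ else paste(v, collapse = "|")
    })
  }
  write_tegc_tsv(out, path, comments = comments, list_sep = ";")
}

round_cols <- function(x, digits, cols) {
  dplyr::mutate(x, dplyr::across(dplyr::any_of(cols), ~ round(.x, digits)))
}

# report-layer rounding: GC%/fractions to 1 decimal, coefficients to 3,
# p-values to 3 significant digits; internal precision stays full
round_report <- function(x) {
  x <- round_cols(x, 1, c("gc_genome", "gc_rep", "gc_nonrep", "gc_te",
                          "gc_te_overall", "gc_class1", "gc_class2",
                          "gc_pooled", "gc_mean_of_species", "gc_percent",
                          "te_percent"))
  x <- round_cols(x, 3, c("repeat_fraction", "coefficient"))
  if ("p_value" %in% names(x)) x$p_value <- signif(x$p_value, 3)
  x
}
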