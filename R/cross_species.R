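species_table_columns <- c(
  "species_id", "short_code", "lineage_flags", "c_values_pg",
  "assembly_size_mb", "gc_genome", "te_percent", "gc_te",
  "gc_rep", "gc_nonrep"
)

#' Load a cross-species metadata table
#'
#' Reads the per-species trait table used by the correlation analyses: one
#' row per species with lineage flags, cytological genome sizes (C-values),
#' assembly size, genomic GC, TE fraction and consensus TE GC. Multiple
#' C-value measurements for one species sit in a single cell separated by
#' `;` (they are later averaged with [mean_c_value()]); lineage flags are
#' `|`-separated. Empty cells and `.` are missing values, never zeros.
#'
#' @param path Path to a TSV file with a header row. Recognised columns:
#'   `species_id`, `short_code`, `lineage_flags`, `c_values_pg`,
#'   `assembly_size_mb`, `gc_genome`, `te_percent`, `gc_te`, `gc_rep`,
#'   `gc_nonrep`. Unknown columns are kept with a warning.
#' @return A tibble with typed columns; `c_values_pg` and `lineage_flags`
#'   are list-columns (numeric / character vectors per species).
#' @export
load_species_table <- function(path) {
  raw <- readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = c("", ".", "NA"), comment = "#", progress = FALSE
  )
  if (!"species_id" %in% names(raw)) {
    abort("species table must have a 'species_id' column",
          class = "tegc_format_error")
  }
  unknown <- setdiff(names(raw), species_table_columns)
  if (length(unknown) > 0) {
    warn(paste0("unknown species-table column(s) kept as text: ",
                paste(unknown, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("unparseable %s '%s' at species table line %d",
                    col, x[bad[1]], bad[1] + 1L),
            class = "tegc_format_error")
    }
    out
  }
  out <- raw
  for (col in intersect(
    c("assembly_size_mb", "gc_genome", "te_percent", "gc_te",
      "gc_rep", "gc_nonrep"), names(out))) {
    out[[col]] <- parse_num(out[[col]], col)
  }
  if ("c_values_pg" %in% names(out)) {
    out$c_values_pg <- purrr::imap(out$c_values_pg, function(cell, i) {
      if (is.na(cell)) return(numeric(0))
      v <- suppressWarnings(as.numeric(stringr::str_split_1(cell, ";")))
      if (anyNA(v)) {
        abort(sprintf("unparseable c_values_pg '%s' at species table line %d",
                      cell, i + 1L), class = "tegc_format_error")
      }
      if (any(v <= 0)) {
        abort(sprintf("non-positive C-value at species table line %d", i + 1L),
              class = "tegc_format_error")
      }
      v
    })
  } else {
    out$c_values_pg <- rep(list(numeric(0)), nrow(out))
  }
  if ("lineage_flags" %in% names(out)) {
    out$lineage_flags <- purrr::map(out$lineage_flags, function(cell) {
      if (is.na(cell)) character(0) else stringr::str_split_1(cell, stringr::fixed("|"))
    })
  } else {
    out$lineage_flags <- rep(list(character(0)), nrow(out))
  }
  pct <- intersect(c("gc_genome", "te_percent", "gc_te", "gc_rep", "gc_nonrep"),
                   names(out))
  for (col in pct) {
    bad <- which(!is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 100))
    if (length(bad) > 0) {
      abort(sprintf("%s outside [0, 100] at species table line %d",
                    col, bad[1] + 1L), class = "tegc_format_error")
    }
  }
  out
}

#' Average repeated C-value measurements
#'
#' The Animal Genome Size Database often lists several cytological
#' measurements per species; analyses use their arithmetic mean. An empty
#' measurement list gives `NA` (missing, excluded pairwise downstream).
#'
#' @param c_values A list-column of numeric vectors (as in
#'   [load_species_table()]) or a single numeric vector.
#' @return Numeric vector of per-species mean C-values in pg.
#' @examples
#' mean_c_value(list(c(1.0, 1.4), 2.0, numeric(0)))
#' @export
mean_c_value <- function(c_values) {
  if (!is.list(c_values)) c_values <- list(c_values)
  purrr::map_dbl(c_values, function(v) {
    if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Filter a species panel with an auditable exclusion log
#'
#' Applies named filters from a fixed registry and records every excluded
#' species with the reason, so that analysis provenance (most importantly the
#' salmonid exclusion: salmonids carry an extra lineage-specific whole-genome
#' duplication and extremely amplified, GC-rich rRNA arrays that distort
#' size-GC correlations) is always reconstructable. Available filters:
#'
#' * `exclude_salmonids` — drop species whose lineage flags contain
#'   `salmonid`;
#' * `teleosts_only` — keep species flagged `teleost`;
#' * `require_variables` — drop species missing any of `require_vars`.
#'
#' @param records A species tibble from [load_species_table()].
#' @param filters Character vector of filter names (possibly empty).
#' @param require_vars Columns that must be non-missing (used by the
#'   `require_variables` filter; supplying it implies the filter).
#' @return The retained subset, with the exclusion log (tibble `species_id`,
#'   `filter`, `reason`) attached as attribute `"exclusion_log"` (retrieve
#'   with [exclusion_log()]) and the filter description as
#'   `"filter_description"`.
#' @export
apply_filters <- function(records, filters = character(), require_vars = character()) {
  known <- c("exclude_salmonids", "teleosts_only", "require_variables")
  bad <- setdiff(filters, known)
  if (length(bad) > 0) {
    abort(paste0("unknown filter(s): ", paste(bad, collapse = ", "),
                 " (available: ", paste(known, collapse = ", "), ")"),
          class = "tegc_config_error")
  }
  if (length(require_vars) > 0) filters <- union(filters, "require_variables")
  log <- tibble::tibble(species_id = character(), filter = character(),
                        reason = character())
  keep <- records
  drop_rows <- function(keep, log, drop_idx, filter, reason) {
    if (length(drop_idx) > 0) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        species_id = keep$species_id[drop_idx], filter = filter, reason = reason
      ))
      keep <- keep[-drop_idx, , drop = FALSE]
    }
    list(keep = keep, log = log)
  }
  if ("exclude_salmonids" %in% filters) {
    idx <- which(purrr::map_lgl(keep$lineage_flags, ~ "salmonid" %in% .x))
    res <- drop_rows(keep, log, idx, "exclude_salmonids",
                     "salmonid-specific WGD with amplified GC-rich rDNA")
    keep <- res$keep; log <- res$log
  }
  if ("teleosts_only" %in% filters) {
    idx <- which(!purrr::map_lgl(keep$lineage_flags, ~ "teleost" %in% .x))
    res <- drop_rows(keep, log, idx, "teleosts_only", "not flagged teleost")
    keep <- res$keep; log <- res$log
  }
  if ("require_variables" %in% filters) {
    for (v in require_vars) {
      if (!v %in% names(keep)) {
        abort(paste0("require_variables: no column '", v, "'"),
              class = "tegc_config_error")
      }
      miss <- if (is.list(keep[[v]])) {
        purrr::map_lgl(keep[[v]], ~ length(.x) == 0)
      } else {
        is.na(keep[[v]])
      }
      res <- drop_rows(keep, log, which(miss), "require_variables",
                       paste0("missing ", v))
      keep <- res$keep; log <- res$log
    }
  }
  attr(keep, "exclusion_log") <- log
  attr(keep, "filter_description") <-
    if (length(filters) == 0) "none" else paste(filters, collapse = ",")
  keep
}

#' @rdname apply_filters
#' @param x A tibble returned by [apply_filters()].
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusion_log") %||%
    tibble::tibble(species_id = character(), filter = character(),
                   reason = character())
}

#' Correlate two species-level variables
#'
#' Computes the correlation between two columns of a species table over
#' pairwise-complete observations (no imputation), with a two-sided p-value.
#' Pearson uses the usual t test; Spearman uses mid-ranks for ties and, for
#' small untied samples, the exact permutation null distribution (the
#' asymptotic approximation otherwise). Genome sizes are heavy-tailed across
#' fish, so Spearman is the default method.
#'
#' @param records A species tibble (possibly from [apply_filters()]).
#' @param x_var,y_var Column names. `"c_value_pg"` may be used as a derived
#'   variable (mean of `c_values_pg` via [mean_c_value()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param analysis Optional analysis label carried into the result.
#' @return A one-row tibble of class `gc_correlation`: `analysis`, `x_var`,
#'   `y_var`, `method`, `n`, `coefficient`, `p_value`, `filter` and
#'   `excluded` (list-column of species dropped for missing values in this
#'   pair). Zero variance in either variable yields `NA` coefficient with a
#'   warning; fewer than 3 complete pairs is an error.
#' @examples
#' d <- tibble::tibble(species_id = letters[1:4], x = 1:4, y = c(2, 4, 6, 8))
#' correlate(d, "x", "y", method = "pearson")
#' @export
correlate <- function(records, x_var, y_var,
                      method = c("spearman", "pearson"),
                      analysis = paste0(y_var, "~", x_var)) {
  method <- match.arg(method)
  x <- derived_variable(records, x_var)
  y <- derived_variable(records, y_var)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    abort(sprintf("fewer than 3 complete (%s, %s) pairs (n=%d)", x_var, y_var, n),
          class = "tegc_insufficient_data_error")
  }
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warn(sprintf("zero variance in %s correlation pair: coefficient undefined",
                 analysis), class = "tegc_zero_variance_warning")
    coefficient <- NA_real_; p_value <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(xs, ys, method = method,
                                    alternative = "two.sided"))
    coefficient <- unname(ct$estimate)
    p_value <- ct$p.value
  }
  out <- tibble::tibble(
    analysis = analysis, x_var = x_var, y_var = y_var, method = method,
    n = n, coefficient = coefficient, p_value = p_value,
    filter = attr(records, "filter_description") %||% "none",
    excluded = list(records$species_id[!ok])
  )
  class(out) <- c("gc_correlation", class(out))
  out
}

derived_variable <- function(records, var) {
  if (var == "c_value_pg") {
    if (!"c_values_pg" %in% names(records)) {
      abort("no c_values_pg column to derive c_value_pg from",
            class = "tegc_config_error")
    }
    return(mean_c_value(records$c_values_pg))
  }
  if (!var %in% names(records)) {
    abort(paste0("no column '", var, "' in species table"),
          class = "tegc_config_error")
  }
  v <- records[[var]]
  if (!is.numeric(v)) {
    abort(paste0("column '", var, "' is not numeric"),
          class = "tegc_config_error")
  }
  v
}

#' Run the full cross-species correlation suite
#'
#' Executes the standard set of comparative-composition analyses on a species
#' table, each over its pairwise-complete subset, with both correlation
#' methods and full filter provenance:
#'
#' * `size_te` — genome size (mean C-value, pg) vs. TE% of the genome;
#' * `size_gc_excl_salmonids` — C-value vs. genomic GC%, salmonids excluded;
#' * `size_gc_incl_salmonids` — the same without the exclusion, quantifying
#'   how the GC-inflated rediploidised salmonid genomes distort the trend;
#' * `asmsize_gc` — assembly size (Mb) vs. genomic GC%;
#' * `gcte_gcg` — consensus TE GC (GC_TE) vs. genomic GC%;
#' * `gcrep_gcnonrep` — GC of the repeat-masked vs. non-repetitive fraction.
#'
#' A per-species GC_TE vs. GC_G sign table (which species have GC-poorer TE
#' consensus than their genome) is attached as attribute `"sign_table"`.
#' Analyses lacking data are skipped with a logged reason (attribute
#' `"skipped"`), never silently. Output is fully deterministic.
#'
#' @param records A species tibble from [load_species_table()].
#' @param methods Correlation methods to run (default both, Spearman first).
#' @return A tibble of class `gc_analysis_suite`, one row per analysis and
#'   method, with [correlate()] columns.
#' @export
analysis_suite <- function(records, methods = c("spearman", "pearson")) {
  plan <- tibble::tibble(
    analysis = c("size_te", "size_gc_excl_salmonids", "size_gc_incl_salmonids",
                 "asmsize_gc", "gcte_gcg", "gcrep_gcnonrep"),
    x_var = c("c_value_pg", "c_value_pg", "c_value_pg",
              "assembly_size_mb", "gc_genome", "gc_nonrep"),
    y_var = c("te_percent", "gc_genome", "gc_genome",
              "gc_genome", "gc_te", "gc_rep"),
    filters = list("none", "exclude_salmonids", "none", "none", "none", "none")
  )
  skipped <- tibble::tibble(analysis = character(), reason = character())
  rows <- purrr::pmap(plan, function(analysis, x_var, y_var, filters) {
    flt <- setdiff(unlist(filters), "none")
    recs <- apply_filters(records, filters = flt)
    purrr::map(methods, function(m) {
      tryCatch(
        correlate(recs, x_var, y_var, method = m, analysis = analysis),
        tegc_insufficient_data_error = function(e) {
          skipped <<- dplyr::bind_rows(skipped, tibble::tibble(
            analysis = analysis, reason = conditionMessage(e)))
          NULL
        },
        tegc_config_error = function(e) {
          skipped <<- dplyr::bind_rows(skipped, tibble::tibble(
            analysis = analysis, reason = conditionMessage(e)))
          NULL
        }
      )
    })
  })
  out <- dplyr::bind_rows(purrr::compact(purrr::list_flatten(rows)))
  if (nrow(skipped) > 0) {
    inform(paste0("skipped analyses: ",
                  paste(unique(skipped$analysis), collapse = ", ")))
  }
  sign_table <- NULL
  if (all(c("gc_te", "gc_genome") %in% names(records))) {
    sign_table <- records |>
      dplyr::filter(!is.na(.data$gc_te), !is.na(.data$gc_genome)) |>
      dplyr::transmute(
        species_id = .data$species_id,
        gc_genome = .data$gc_genome, gc_te = .data$gc_te,
        gc_te_minus_gc_genome = .data$gc_te - .data$gc_genome,
        te_gc_poorer = .data$gc_te < .data$gc_genome
      )
  }
  attr(out, "sign_table") <- sign_table
  attr(out, "skipped") <- unique(skipped)
  class(out) <- c("gc_analysis_suite", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.gc_analysis_suite <- function(x, ...) {
  out <- dplyr::select(x, -"excluded")
  class(out) <- class(tibble::tibble())
  out
}

#' @exportS3Method generics::glance
glance.gc_analysis_suite <- function(x, ...) {
  sp <- dplyr::filter(x, .data$method == x$method[1])
  tibble::tibble(
    n_analyses = dplyr::n_distinct(x$analysis),
    n_skipped = nrow(attr(x, "skipped") %||% tibble::tibble()),
    n_positive = sum(sp$coefficient > 0, na.rm = TRUE),
    n_negative = sum(sp$coefficient < 0, na.rm = TRUE),
    min_p = min(x$p_value, na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.gc_correlation <- function(x, ...) {
  out <- dplyr::select(x, -"excluded")
  class(out) <- class(tibble::tibble())
  out
}
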