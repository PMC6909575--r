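#' Default TE classification map
#'
#' Maps the top-level token of a RepeatMasker-style classification string
#' (the part after `#`, before `/`) onto the Class I / Class II dichotomy.
#' Retroelements (LINE, SINE, LTR, DIRS, Retroposon, Penelope) are Class I;
#' cut-and-paste and rolling-circle transposons (`DNA/*`, `RC/*` Helitrons)
#' are Class II; simple repeats, low-complexity sequence, satellites,
#' structural RNAs and artefacts are non-TE and are excluded from every TE
#' statistic. Penelope is classed I by mechanism (retroelement) and Helitrons
#' II by the standard two-class convention; both assignments are editable by
#' passing a modified map.
#'
#' @return A tibble with columns `prefix` and `te_class`.
#' @export
default_te_classes <- function() {
  tibble::tibble(
    prefix = c("LINE", "SINE", "LTR", "DIRS", "Retroposon", "Penelope",
               "DNA", "RC",
               "Simple_repeat", "Low_complexity", "Satellite",
               "rRNA", "tRNA", "snRNA", "scRNA", "ARTEFACT"),
    te_class = c(rep("I", 6), rep("II", 2), rep("non-TE", 8))
  )
}

#' Parse RepeatMasker-style TE headers
#'
#' Splits `name#Class/Superfamily` headers (the dialect used by FishTEDB and
#' Repbase-derived libraries) into a family name and a normalised TE taxonomy.
#' The classification string after the first `#` is matched against a class
#' map (see [default_te_classes()]). The group label is the order token for
#' Class I elements (LTR, LINE, SINE, DIRS, ...) and the superfamily token
#' after `/` for Class II, with composite names collapsed to their leading
#' token (`CMC-EnSpm` to `CMC`, `TcMar-Tc1` to `TcMar`). Anything unparseable
#' is kept, classed `unknown` with group `Unknown`; the raw classification
#' string is always retained for audit.
#'
#' @param header Character vector of header strings (without the leading `>`).
#' @param class_map Classification map, defaulting to [default_te_classes()].
#' @return A tibble with columns `name`, `te_class` (`"I"`, `"II"`,
#'   `"non-TE"` or `"unknown"`), `group` and `superfamily_raw`.
#' @examples
#' parse_te_header(c("Tc1-1_DR#DNA/TcMar-Tc1", "ERV1-3_LO#LTR/ERV1", "someRepeat"))
#' @export
parse_te_header <- function(header, class_map = default_te_classes()) {
  header <- trimws(header)
  has_hash <- stringr::str_detect(header, stringr::fixed("#"))
  name <- ifelse(has_hash, stringr::str_extract(header, "^[^#]*"), header)
  raw <- ifelse(has_hash, stringr::str_remove(header, "^[^#]*#"), "")
  top <- stringr::str_extract(raw, "^[^/]*")
  sub <- ifelse(
    stringr::str_detect(raw, stringr::fixed("/")),
    stringr::str_remove(raw, "^[^/]*/"), ""
  )
  te_class <- class_map$te_class[match(top, class_map$prefix)]
  te_class[is.na(te_class) | !nzchar(raw)] <- "unknown"
  # leading token of the superfamily: CMC-EnSpm -> CMC, TcMar-Tc1 -> TcMar
  sub_lead <- stringr::str_extract(sub, "^[^-]*")
  group <- dplyr::case_when(
    te_class == "I" ~ top,
    te_class == "II" & nzchar(sub_lead) ~ sub_lead,
    te_class == "non-TE" ~ top,
    .default = "Unknown"
  )
  group[is.na(group) | !nzchar(group)] <- "Unknown"
  tibble::tibble(
    name = name, te_class = te_class, group = group, superfamily_raw = raw
  )
}

#' Load a TE consensus library
#'
#' Reads a consensus-sequence FASTA library (FishTEDB / Repbase dialect) and
#' parses each header into TE taxonomy. Record order is preserved.
#' Zero-length records are retained in the table but contribute nothing to
#' downstream GC pooling.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param class_map Classification map, defaulting to [default_te_classes()].
#' @return A tibble with one row per consensus: `name`, `te_class`, `group`,
#'   `superfamily_raw`, `length`, `residues`.
#' @export
load_te_library <- function(path, class_map = default_te_classes()) {
  fa <- read_fasta(path)
  # taxonomy lives in the first header token; free-text description is ignored
  parsed <- parse_te_header(fa$seq_id, class_map = class_map)
  dplyr::bind_cols(
    parsed,
    tibble::tibble(length = nchar(fa$residues), residues = fa$residues)
  )
}

per_family_gc <- function(lib) {
  # unambiguous bases only (U as T); ambiguity codes such as S never count
  gc_n <- stringr::str_count(lib$residues, "[GCgc]")
  counted <- stringr::str_count(lib$residues, "[ACGTUacgtu]")
  dplyr::mutate(lib, counted_bases = counted, gc_count = gc_n,
                gc = ifelse(counted > 0, 100 * gc_n / counted, NA_real_))
}

#' Per-species consensus GC profile
#'
#' Pools base counts over a species' TE consensus library — each family
#' counted exactly once, deliberately unweighted by genomic copy number so
#' that the statistic reflects elements at their insertion-time state rather
#' than their present genomic location — and reports the overall consensus GC
#' (GC_TE) together with Class I / Class II and per-group breakdowns. Non-TE
#' entries (simple repeats, satellites, structural RNAs) are always excluded.
#' Families of unknown class count toward `gc_te_overall` but toward neither
#' class value.
#'
#' @param lib A library tibble from [load_te_library()] (or any data frame
#'   with `name`, `te_class`, `group`, `residues`).
#' @param species_id Optional species label carried into the profile.
#' @param include Character vector of classes pooled into `gc_te_overall`
#'   (default `c("I", "II", "unknown")`).
#' @return A one-row tibble of class `te_profile`: `species_id`,
#'   `n_families` (TE families with countable bases), `gc_te_overall`,
#'   `gc_class1`, `gc_class2` (`NA` when a class is absent) and `per_group`,
#'   a nested tibble (`group`, `te_class`, `n_families`, `counted_bases`,
#'   `gc_count`, `gc_percent`).
#' @examples
#' lib <- tibble::tibble(
#'   name = c("f1", "f2"), te_class = c("II", "I"),
#'   group = c("TcMar", "LTR"), superfamily_raw = c("DNA/TcMar", "LTR/Gypsy"),
#'   length = c(4L, 4L), residues = c("AAAA", "GGGG")
#' )
#' species_gc_te(lib)
#' @export
species_gc_te <- function(lib, species_id = NA_character_,
                          include = c("I", "II", "unknown")) {
  te <- dplyr::filter(per_family_gc(lib), .data$te_class != "non-TE")
  pooled <- dplyr::filter(te, .data$te_class %in% include)
  if (nrow(te) == 0L || sum(te$counted_bases) == 0L) {
    warn(paste0("library has no countable TE sequence",
                if (!is.na(species_id)) paste0(" (", species_id, ")")),
         class = "tegc_empty_library_warning")
  }
  pool_gc <- function(d) {
    cb <- sum(d$counted_bases)
    if (cb > 0) 100 * sum(d$gc_count) / cb else NA_real_
  }
  per_group <- te |>
    dplyr::filter(.data$counted_bases > 0) |>
    dplyr::group_by(.data$group, .data$te_class) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      counted_bases = sum(.data$counted_bases),
      gc_count = sum(.data$gc_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(gc_percent = 100 * .data$gc_count / .data$counted_bases) |>
    dplyr::arrange(.data$te_class, .data$group)
  out <- tibble::tibble(
    species_id = species_id,
    n_families = sum(te$counted_bases > 0),
    gc_te_overall = pool_gc(pooled),
    gc_class1 = pool_gc(dplyr::filter(te, .data$te_class == "I")),
    gc_class2 = pool_gc(dplyr::filter(te, .data$te_class == "II")),
    per_group = list(per_group)
  )
  class(out) <- c("te_profile", class(out))
  out
}

#' Pool per-group consensus GC across species
#'
#' Aggregates the per-group GC of several species profiles into one
#' cross-species table. Two aggregation conventions are computed side by
#' side: `gc_pooled` sums base counts per group over species and then takes
#' GC (each consensus base weighted equally, the default convention), and
#' `gc_mean_of_species` averages the per-species group GC values unweighted
#' (each species weighted equally). The two agree exactly when every species
#' contributes the same number of counted bases to the group. Groups absent
#' from every species are omitted.
#'
#' @param profiles A `te_profile` tibble (rows from [species_gc_te()],
#'   combined with [dplyr::bind_rows()]).
#' @return A tibble with one row per (group, class): `group`, `te_class`,
#'   `n_families`, `n_species`, `gc_pooled`, `gc_mean_of_species`.
#' @export
pool_groups_across_species <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  tidyr::unnest(
    dplyr::select(profiles, "species_id", "per_group"), "per_group"
  ) |>
    dplyr::group_by(.data$group, .data$te_class) |>
    dplyr::summarise(
      n_families = sum(.data$n_families),
      n_species = dplyr::n_distinct(.data$species_id),
      gc_pooled = 100 * sum(.data$gc_count) / sum(.data$counted_bases),
      gc_mean_of_species = mean(.data$gc_percent),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$te_class, .data$group)
}

#' Class I minus Class II consensus GC contrast
#'
#' The signed difference `gc_class1 - gc_class2` in percentage points:
#' positive when retrotransposons are GC-richer than DNA transposons, the
#' pattern typical of fish consensus libraries.
#'
#' @param profile A one-row `te_profile` from [species_gc_te()], or any data
#'   frame with `gc_class1` and `gc_class2` columns.
#' @return Numeric vector of percentage-point differences (`NA`, with a
#'   warning, when either class GC is undefined).
#' @examples
#' class_contrast(tibble::tibble(gc_class1 = 45.6, gc_class2 = 40.1))
#' @export
class_contrast <- function(profile) {
  d <- profile$gc_class1 - profile$gc_class2
  if (anyNA(d)) {
    warn("class contrast undefined where a class has no countable families",
         class = "tegc_undefined_contrast_warning")
  }
  d
}

#' @exportS3Method generics::tidy
tidy.te_profile <- function(x, ...) {
  tidyr::unnest(dplyr::select(x, "species_id", "per_group"), "per_group")
}

#' @exportS3Method generics::glance
glance.te_profile <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    n_families = sum(x$n_families),
    gc_te_overall = 100 * sum(purrr::map_dbl(x$per_group, ~ sum(.x$gc_count))) /
      sum(purrr::map_dbl(x$per_group, ~ sum(.x$counted_bases))),
    class_contrast = mean(class_contrast(x), na.rm = TRUE)
  )
}
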