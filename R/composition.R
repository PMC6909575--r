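#' Tally nucleotide composition of a sequence set
#'
#' Counts A/C/G/T separately by case (uppercase = unmasked, lowercase =
#' soft-masked) across all sequences, plus `N`/`n` and everything else. These
#' tallies are the atom from which every GC statistic in the package derives.
#' `U`/`u` (RNA alphabet, present in some consensus libraries) are counted as
#' `T`/`t` of the same case. IUPAC ambiguity codes (including `S` = G/C) and
#' gap symbols land in `other_count` and never enter a GC numerator or
#' denominator.
#'
#' @param seqs A data frame with a `residues` column (as returned by
#'   [read_fasta()]) or a character vector of sequences.
#' @return A one-row tibble with integer columns `a_upper`, `c_upper`,
#'   `g_upper`, `t_upper`, `a_lower`, `c_lower`, `g_lower`, `t_lower`,
#'   `n_count`, `other_count` and `total_length`. The first ten columns always
#'   sum to `total_length`.
#' @examples
#' count_bases("ATGCatgc")
#' count_bases(c("NNRYSW", "UUuu"))
#' @export
count_bases <- function(seqs) {
  x <- residues_of(seqs)
  tally <- function(ch) sum(stringr::str_count(x, stringr::fixed(ch)))
  a_up <- tally("A"); c_up <- tally("C"); g_up <- tally("G")
  t_up <- tally("T") + tally("U")
  a_lo <- tally("a"); c_lo <- tally("c"); g_lo <- tally("g")
  t_lo <- tally("t") + tally("u")
  n_ct <- tally("N") + tally("n")
  total <- sum(nchar(x))
  known <- a_up + c_up + g_up + t_up + a_lo + c_lo + g_lo + t_lo + n_ct
  tibble::tibble(
    a_upper = a_up, c_upper = c_up, g_upper = g_up, t_upper = t_up,
    a_lower = a_lo, c_lower = c_lo, g_lower = g_lo, t_lower = t_lo,
    n_count = n_ct, other_count = total - known, total_length = total
  )
}

residues_of <- function(seqs) {
  if (is.data.frame(seqs)) {
    if (!"residues" %in% names(seqs)) {
      abort("data-frame input must have a 'residues' column",
            class = "tegc_input_error")
    }
    seqs$residues
  } else if (is.character(seqs)) {
    seqs
  } else {
    abort("seqs must be a data frame with 'residues' or a character vector",
          class = "tegc_input_error")
  }
}

#' GC percentage from base tallies
#'
#' Computes GC% = 100 (G + C) / (A + C + G + T) over a chosen case fraction of
#' a [count_bases()] tally. `N`, ambiguity codes and gaps are excluded from
#' both numerator and denominator; when the denominator is zero the GC value
#' is undefined and reported as `NA` (a value, not an error).
#'
#' @param counts A base-count tibble from [count_bases()] (or a data frame /
#'   character vector of sequences, tallied on the fly).
#' @param fraction Which residues to use: `"all"`, `"masked_only"` (lowercase,
#'   i.e. the repeat-masked fraction) or `"unmasked_only"` (uppercase).
#' @return A one-row tibble with `gc_percent` (`NA` when undefined),
#'   `counted_bases` (unambiguous A/C/G/T used) and `total_length` (for
#'   case-restricted fractions this equals `counted_bases`, since `N` and
#'   other symbols are not attributed to a case class).
#' @examples
#' gc_percent(count_bases("ATGCN"))
#' gc_percent(count_bases("aattGGCC"), fraction = "masked_only")
#' @export
gc_percent <- function(counts, fraction = c("all", "masked_only", "unmasked_only")) {
  fraction <- match.arg(fraction)
  counts <- as_base_counts(counts)
  up_gc <- counts$g_upper + counts$c_upper
  up_at <- counts$a_upper + counts$t_upper
  lo_gc <- counts$g_lower + counts$c_lower
  lo_at <- counts$a_lower + counts$t_lower
  gc <- switch(fraction,
    all = up_gc + lo_gc, masked_only = lo_gc, unmasked_only = up_gc)
  denom <- gc + switch(fraction,
    all = up_at + lo_at, masked_only = lo_at, unmasked_only = up_at)
  tibble::tibble(
    gc_percent = if (denom > 0) 100 * gc / denom else NA_real_,
    counted_bases = denom,
    total_length = if (fraction == "all") counts$total_length else denom
  )
}

as_base_counts <- function(counts) {
  cols <- c("a_upper", "c_upper", "g_upper", "t_upper",
            "a_lower", "c_lower", "g_lower", "t_lower")
  if (is.data.frame(counts) && all(cols %in% names(counts))) {
    if (nrow(counts) != 1L) {
      abort("base-count input must have exactly one row",
            class = "tegc_input_error")
    }
    counts
  } else {
    count_bases(counts)
  }
}

#' Partition a soft-masked assembly into repetitive and non-repetitive GC
#'
#' Splits a soft-masked genome (lowercase = masked by RepeatMasker or
#' equivalent, as in Ensembl "sm" dumps) into its repeat-masked and unmasked
#' fractions and reports the genomic GC (GC_G), the GC of the repetitive
#' fraction (GC_REP, lowercase residues, repeats including low-complexity
#' regions) and of the non-repetitive remainder (GC_NONREP, uppercase). The
#' three satisfy the exact weighted-mean identity
#' `counted_rep * gc_rep + counted_nonrep * gc_nonrep =
#' (counted_rep + counted_nonrep) * gc_genome` whenever both fractions are
#' defined. Uppercase `N` runs (assembly gaps) are excluded entirely;
#' hard-masked (N-for-repeat) inputs are not supported.
#'
#' @param seqs A data frame with a `residues` column, a character vector of
#'   sequences, or a pre-computed [count_bases()] tally.
#' @return A one-row tibble with `gc_genome`, `gc_rep`, `gc_nonrep`
#'   (`NA` when a fraction has no counted bases), `repeat_fraction`
#'   (masked share of counted A/C/G/T bases), `counted_rep` and
#'   `counted_nonrep`.
#' @examples
#' partition_genome("aattGGCC")
#' @export
partition_genome <- function(seqs) {
  counts <- as_base_counts(seqs)
  all_gc <- gc_percent(counts, "all")
  rep_gc <- gc_percent(counts, "masked_only")
  non_gc <- gc_percent(counts, "unmasked_only")
  counted <- rep_gc$counted_bases + non_gc$counted_bases
  repeat_fraction <- if (counted > 0) rep_gc$counted_bases / counted else NA_real_
  if (isTRUE(repeat_fraction == 0)) {
    warn("no soft-masked (lowercase) residues found: input looks fully unmasked",
         class = "tegc_unmasked_warning")
  }
  tibble::tibble(
    gc_genome = all_gc$gc_percent,
    gc_rep = rep_gc$gc_percent,
    gc_nonrep = non_gc$gc_percent,
    repeat_fraction = repeat_fraction,
    counted_rep = rep_gc$counted_bases,
    counted_nonrep = non_gc$counted_bases
  )
}

#' Per-assembly composition table
#'
#' Convenience wrapper applying [partition_genome()] to each of several FASTA
#' files plus a per-sequence breakdown for one file, in the shape used by the
#' command-line reports.
#'
#' @param paths Character vector of soft-masked FASTA paths.
#' @return A tibble with one row per file: `assembly`, `n_seqs`,
#'   `total_length`, `counted_bases`, `gc_genome`, `gc_rep`, `gc_nonrep`,
#'   `repeat_fraction`.
#' @export
genome_stats <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    seqs <- read_fasta(p)
    counts <- count_bases(seqs)
    part <- partition_genome(counts)
    dplyr::bind_cols(
      tibble::tibble(
        assembly = sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(p)),
        n_seqs = nrow(seqs),
        total_length = counts$total_length,
        counted_bases = part$counted_rep + part$counted_nonrep
      ),
      part
    )
  })
}

#' Isochore band classification
#'
#' Assigns a GC percentage to one of the classical isochore families. Fish and
#' amphibian genomes typically occupy only two neighbouring light bands
#' (AT/GC-homogeneous), whereas avian and mammalian genomes span all five
#' (AT/GC-heterogeneous). The published band definitions are approximate and
#' leave one-point gaps between bands; the default boundaries here close those
#' gaps with half-open intervals so that classification is a total, monotone
#' function on \[0, 100\]: sub-L1 \[0, 34), L1 \[34, 37), L2 \[37, 41),
#' H1 \[41, 46), H2 \[46, 53), H3 \[53, 100\].
#'
#' @param gc Numeric vector of GC percentages in \[0, 100\]; `NA` passes
#'   through.
#' @param boundaries Increasing numeric vector of the five lower band limits
#'   of L1, L2, H1, H2, H3 (default `c(34, 37, 41, 46, 53)`).
#' @return An ordered factor with levels `sub-L1 < L1 < L2 < H1 < H2 < H3`.
#' @examples
#' isochore_band(c(38.5, 55, 40.5))
#' @export
isochore_band <- function(gc, boundaries = c(34, 37, 41, 46, 53)) {
  stopifnot(is.numeric(gc), length(boundaries) == 5L, !is.unsorted(boundaries))
  bad <- !is.na(gc) & (gc < 0 | gc > 100)
  if (any(bad)) {
    abort(paste0("GC% outside [0, 100]: ", paste(gc[bad], collapse = ", ")),
          class = "tegc_domain_error")
  }
  labels <- c("sub-L1", "L1", "L2", "H1", "H2", "H3")
  idx <- findInterval(gc, boundaries) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Convert a cytological C-value to megabases
#'
#' Genome sizes are reported either cytologically (C-value, picograms) or as
#' assembly lengths (Mb); this converts the former to the latter with the
#' conventional ~978 Mb per pg of double-stranded DNA. The constant is a
#' configurable default rather than a fixed property because it is only used
#' for cross-checks between the two size scales.
#'
#' @param c_value_pg Positive numeric vector of C-values in picograms.
#' @param mb_per_pg Positive conversion constant (default 978 Mb/pg).
#' @return `c_value_pg * mb_per_pg`, in megabases.
#' @examples
#' cvalue_to_mb(1.4)
#' @export
cvalue_to_mb <- function(c_value_pg, mb_per_pg = 978) {
  if (any(!is.na(c_value_pg) & c_value_pg <= 0) || mb_per_pg <= 0) {
    abort("C-value and Mb-per-pg constant must be positive",
          class = "tegc_domain_error")
  }
  c_value_pg * mb_per_pg
}
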