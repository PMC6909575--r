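#' Default synthetic TE group profile
#'
#' The six TE groups simulated in synthetic consensus libraries, three per
#' class, with target consensus GC values echoing the qualitative ordering
#' seen in fish libraries: DIRS retroelements GC-richest, CMC DNA transposons
#' AT-richest, LTR retrotransposons GC-richer than LINEs. `gc_target` values
#' are raw targets; [generate_panel()] shifts the two classes rigidly so that
#' the pooled Class I - Class II contrast equals the panel's
#' `class1_gc_offset` exactly (see [adjust_group_targets()]).
#'
#' @return A tibble with columns `group`, `te_class`, `classification`
#'   (the header string after `#`), `gc_target` (percent) and `n_families`.
#' @export
default_group_profile <- function() {
  tibble::tibble(
    group = c("DIRS", "LTR", "LINE", "CMC", "TcMar", "hAT"),
    te_class = c("I", "I", "I", "II", "II", "II"),
    classification = c("DIRS/DIRS", "LTR/Gypsy", "LINE/L2",
                       "DNA/CMC-EnSpm", "DNA/TcMar-Tc1", "DNA/hAT-Ac"),
    gc_target = c(53.8, 48, 44, 35.8, 40, 42),
    n_families = 10L
  )
}

#' Rigidly shift class targets to plant an exact class contrast
#'
#' Shifts all Class I group targets by `+d` and all Class II targets by `-d`
#' so that the family-count-weighted mean GC of Class I exceeds Class II by
#' exactly `class1_gc_offset` percentage points, while preserving the
#' relative ordering of groups within each class.
#'
#' @param group_profile A profile tibble as from [default_group_profile()].
#' @param class1_gc_offset Planted Class I minus Class II offset in
#'   percentage points.
#' @return The profile with adjusted `gc_target`.
#' @export
adjust_group_targets <- function(group_profile, class1_gc_offset) {
  w <- group_profile$n_families
  is1 <- group_profile$te_class == "I"
  m1 <- sum(w[is1] * group_profile$gc_target[is1]) / sum(w[is1])
  m2 <- sum(w[!is1] * group_profile$gc_target[!is1]) / sum(w[!is1])
  d <- (class1_gc_offset - (m1 - m2)) / 2
  group_profile$gc_target <- group_profile$gc_target + ifelse(is1, d, -d)
  if (any(group_profile$gc_target < 1 | group_profile$gc_target > 99)) {
    abort("adjusted group GC targets leave (1, 99)", class = "tegc_domain_error")
  }
  group_profile
}

# i.i.d. random DNA as a single string; gc is a proportion in [0, 1]
random_dna <- function(n, gc) {
  if (n == 0L) return("")
  codes <- sample(
    c(65L, 67L, 71L, 84L), n, replace = TRUE,        # A C G T bytes
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
  rawToChar(as.raw(codes))
}

# symmetric substitution: each hit base becomes one of the other three
# uniformly (drifts GC toward 50%; callers record realized truth)
mutate_copy <- function(seq, rate) {
  if (rate <= 0) return(seq)
  codes <- as.integer(charToRaw(seq))
  hit <- which(runif(length(codes)) < rate)
  if (length(hit) > 0) {
    bases <- c(65L, 67L, 71L, 84L)
    cur <- match(codes[hit], bases)
    codes[hit] <- bases[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  rawToChar(as.raw(codes))
}

#' Generate a synthetic TE consensus library
#'
#' Draws, for each group in the profile, `n_families` consensus sequences of
#' random length with bases i.i.d. at the group's target GC, under FishTEDB /
#' RepeatMasker `name#Class/Superfamily` headers. Fully deterministic under a
#' fixed seed.
#'
#' @param group_profile Profile tibble (see [default_group_profile()]); an
#'   optional per-call GC shift should be baked into `gc_target` beforehand.
#' @param seed Integer seed.
#' @param length_range Consensus length range in bp (default 500-5000).
#' @return A list with `library` (a [load_te_library()]-shaped tibble) and
#'   `truth` (per group: `gc_target`, `n_families`, `counted_bases`,
#'   `gc_realized`, `sd_binomial` — the binomial standard deviation of the
#'   realized pooled GC at the drawn lengths).
#' @export
generate_te_library <- function(group_profile, seed,
                                length_range = c(500L, 5000L)) {
  stopifnot(sum(group_profile$n_families) > 0)
  set.seed(seed)
  fams <- tidyr::uncount(group_profile, weights = .data$n_families,
                         .id = "fam_idx")
  lens <- as.integer(round(runif(nrow(fams), length_range[1], length_range[2])))
  residues <- purrr::map2_chr(lens, fams$gc_target / 100, random_dna)
  lib <- tibble::tibble(
    name = sprintf("%s-%d_Syn", fams$group, fams$fam_idx),
    te_class = fams$te_class,
    group = fams$group,
    superfamily_raw = fams$classification,
    length = lens,
    residues = residues
  )
  truth <- lib |>
    dplyr::mutate(gc_target = fams$gc_target,
                  gc_count = stringr::str_count(residues, "[GC]")) |>
    dplyr::group_by(.data$group, .data$te_class) |>
    dplyr::summarise(
      gc_target = .data$gc_target[1],
      n_families = dplyr::n(),
      counted_bases = sum(.data$length),
      gc_count = sum(.data$gc_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gc_realized = 100 * .data$gc_count / .data$counted_bases,
      sd_binomial = 100 * sqrt(.data$gc_target / 100 * (1 - .data$gc_target / 100) /
                                 .data$counted_bases)
    )
  list(library = lib, truth = truth)
}

#' Generate a synthetic soft-masked genome
#'
#' Builds one assembly sequence: an i.i.d. uppercase background at
#' `gc_background`, with TE copies sampled (with replacement) from a
#' consensus library, point-mutated at `copy_mutation_rate`, lowercased
#' (soft-masked) and spliced in at uniform random positions until the
#' repetitive fraction hits `te_percent` exactly (the last copy is truncated
#' to fit). Optional uppercase-N gap runs emulate assembly gaps. No nesting
#' or fragmentation beyond the final truncation is modelled — partition
#' arithmetic is position-independent, so uniform placement suffices for
#' composition statistics.
#'
#' @param library Consensus library tibble (uppercase A/C/G/T residues).
#' @param size_bp Genome length in bp, excluding N gaps.
#' @param gc_background Background GC percent.
#' @param te_percent Target repetitive percentage of `size_bp` (must be
#'   < 100).
#' @param seed Integer seed.
#' @param copy_mutation_rate Per-base substitution probability on inserted
#'   copies (default 0.02; the symmetric model drifts copy GC slightly
#'   toward 50%, which the realized truth reflects).
#' @param n_gaps,gap_length Number and length of inserted `N` runs.
#' @return A list with `genome` (one-row tibble `seq_id`, `description`,
#'   `residues`) and `truth` (planted and realized composition, including
#'   the realized [partition_genome()] quantities).
#' @export
generate_genome <- function(library, size_bp, gc_background, te_percent,
                            seed, copy_mutation_rate = 0.02,
                            n_gaps = 0L, gap_length = 500L) {
  stopifnot(nrow(library) > 0, size_bp > 0)
  if (te_percent >= 100) {
    abort("te_percent must be < 100", class = "tegc_domain_error")
  }
  set.seed(seed)
  te_target <- as.integer(round(size_bp * te_percent / 100))
  if (te_target > size_bp) {
    abort("requested TE bases exceed genome size", class = "tegc_domain_error")
  }
  copies <- character(0)
  if (te_target > 0) {
    total <- 0L
    picks <- integer(0)
    while (total < te_target) {
      i <- sample.int(nrow(library), 1L)
      picks <- c(picks, i)
      total <- total + library$length[i]
    }
    copies <- library$residues[picks]
    overshoot <- total - te_target
    if (overshoot > 0) {
      last <- copies[length(copies)]
      copies[length(copies)] <- substr(last, 1L, nchar(last) - overshoot)
    }
    copies <- vapply(copies, mutate_copy, "", rate = copy_mutation_rate,
                     USE.NAMES = FALSE)
    copies <- tolower(copies)
  }
  bg_len <- size_bp - te_target
  background <- random_dna(bg_len, gc_background / 100)
  residues <- splice_segments(background, copies)
  if (n_gaps > 0L) {
    residues <- splice_segments(residues,
                                rep(strrep("N", gap_length), n_gaps))
  }
  counts <- count_bases(residues)
  part <- suppressWarnings(partition_genome(counts))
  truth <- dplyr::bind_cols(
    tibble::tibble(
      size_bp = size_bp, te_target_bp = te_target,
      n_copies = length(copies),
      te_percent_planted = te_percent,
      gc_background_planted = gc_background,
      sd_gc_background = if (bg_len > 0) {
        100 * sqrt(gc_background / 100 * (1 - gc_background / 100) / bg_len)
      } else NA_real_
    ),
    dplyr::rename_with(part, ~ paste0(.x, "_realized"))
  )
  list(
    genome = tibble::tibble(seq_id = "chr1",
                            description = "synthetic soft-masked assembly",
                            residues = residues),
    truth = truth
  )
}

# splice `segments` into `host` at sorted uniform random cut points
splice_segments <- function(host, segments) {
  k <- length(segments)
  if (k == 0L) return(host)
  n <- nchar(host)
  cuts <- sort(sample.int(n + 1L, k, replace = TRUE) - 1L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  pieces <- substring(host, starts, ends)
  interleaved <- character(2L * k + 1L)
  interleaved[seq(1L, 2L * k + 1L, by = 2L)] <- pieces
  interleaved[seq(2L, 2L * k, by = 2L)] <- segments
  paste(interleaved, collapse = "")
}

#' Specify a synthetic species panel
#'
#' Bundles and validates the parameters of a simulated fish panel. Defaults
#' define the package's reference study conditions: 30 species with
#' assemblies uniform on 1-3 Mb (a scaled-down stand-in for real fish genome
#' sizes), a planted positive size-TE% relation, a planted negative size-GC
#' relation, a +6 percentage-point Class I vs Class II consensus GC offset,
#' and a common species-level GC driver coupling consensus TE GC (and hence
#' GC_REP) to the background GC so that GC_TE tracks GC_G across species.
#' A fifth of species are flagged salmonid and sit off-trend with inflated
#' size and GC, emulating rediploidised, rDNA-amplified salmonid genomes.
#'
#' @param n_species Number of species (default 30).
#' @param seed Integer master seed; per-species substreams are derived from
#'   it so a panel is reproducible species by species.
#' @param size_range_mb Assembly size range in Mb (default `c(1, 3)`).
#' @param te_intercept,te_slope TE% of genome = intercept + slope * size(Mb)
#'   + noise (defaults 10 and 8 %/Mb; planted positive relation).
#' @param gc_intercept,gc_slope Genomic GC% = intercept + slope * size(Mb)
#'   + noise (defaults 48 and -3 %/Mb; planted negative relation).
#' @param class1_gc_offset Planted Class I minus Class II pooled consensus GC
#'   offset in percentage points (default 6).
#' @param group_profile Raw group profile (see [default_group_profile()]).
#' @param noise_sd Gaussian noise SD (percent) on the planted linear
#'   relations (default 1).
#' @param te_gc_coupling Points of consensus-GC shift per point of deviation
#'   of a species' background GC from the panel centre (default 0.5; drives
#'   the positive GC_TE-GC_G and GC_REP-GC_NONREP correlations).
#' @param copy_mutation_rate Substitution rate on inserted TE copies
#'   (default 0.02).
#' @param salmonid_fraction Proportion of species flagged salmonid
#'   (default 0.2).
#' @param salmonid_size_boost_mb,salmonid_gc_boost Off-trend size (+1.5 Mb)
#'   and GC (+4 points) inflation applied to salmonid-flagged species.
#' @param family_length_range Consensus length range in bp.
#' @param n_gaps,gap_length Per-genome N-gap runs (default two runs of
#'   500 bp).
#' @return A validated list of class `panel_spec`.
#' @export
panel_spec <- function(n_species = 30L, seed = 1L,
                       size_range_mb = c(1, 3),
                       te_intercept = 10, te_slope = 8,
                       gc_intercept = 48, gc_slope = -3,
                       class1_gc_offset = 6,
                       group_profile = default_group_profile(),
                       noise_sd = 1,
                       te_gc_coupling = 0.5,
                       copy_mutation_rate = 0.02,
                       salmonid_fraction = 0.2,
                       salmonid_size_boost_mb = 1.5,
                       salmonid_gc_boost = 4,
                       family_length_range = c(500L, 5000L),
                       n_gaps = 2L, gap_length = 500L) {
  stopifnot(
    n_species >= 2, length(size_range_mb) == 2, all(size_range_mb > 0),
    size_range_mb[1] <= size_range_mb[2],
    salmonid_fraction >= 0, salmonid_fraction <= 1,
    copy_mutation_rate >= 0, copy_mutation_rate <= 1,
    noise_sd >= 0, all(group_profile$gc_target >= 0),
    all(group_profile$gc_target <= 100)
  )
  spec <- list(
    n_species = as.integer(n_species), seed = as.integer(seed),
    size_range_mb = size_range_mb,
    te_intercept = te_intercept, te_slope = te_slope,
    gc_intercept = gc_intercept, gc_slope = gc_slope,
    class1_gc_offset = class1_gc_offset,
    group_profile = group_profile,
    noise_sd = noise_sd, te_gc_coupling = te_gc_coupling,
    copy_mutation_rate = copy_mutation_rate,
    salmonid_fraction = salmonid_fraction,
    salmonid_size_boost_mb = salmonid_size_boost_mb,
    salmonid_gc_boost = salmonid_gc_boost,
    family_length_range = family_length_range,
    n_gaps = as.integer(n_gaps), gap_length = as.integer(gap_length)
  )
  structure(spec, class = "panel_spec")
}

species_seed <- function(seed, i, stream) {
  # deterministic per-species substream, kept inside 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + i * 104729 + stream * 15485863) %%
               2147483647)
}

#' Generate a synthetic species panel
#'
#' Simulates a full study panel: per species a soft-masked genome, a TE
#' consensus library and a metadata row, all derived from planted linear
#' relations (size-TE%, size-GC) plus Gaussian noise, with salmonid-flagged
#' species pushed off-trend (larger, GC-richer). The metadata table is
#' directly loadable by [load_species_table()]; its composition columns hold
#' the realized (post-sampling) values so the planted correlations are
#' recoverable by [analysis_suite()]. All planted parameters and realized
#' values, with binomial tolerances, are returned as truth tables.
#'
#' @param spec A [panel_spec()].
#' @param dir Output directory; when given, writes `genomes/<code>.fa.gz`,
#'   `te_libs/<code>.fa`, `species_table.tsv`, `truth_species.tsv`,
#'   `truth_groups.tsv` and `truth_panel_groups.tsv`. When `NULL`
#'   (default) everything stays in memory.
#' @return A list of class `te_panel` with elements `species` (metadata
#'   tibble), `truth_species`, `truth_groups` (per species x group),
#'   `panel_groups` (per-group panel-level expected pooled GC with binomial
#'   SDs), `group_targets` (class-adjusted panel targets), `spec`, and —
#'   when `dir` is `NULL` — `libraries` and `genomes` (named lists of
#'   tibbles); with `dir` set, `paths` instead.
#' @export
generate_panel <- function(spec = panel_spec(), dir = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_species
  set.seed(spec$seed)
  size_mb <- runif(n, spec$size_range_mb[1], spec$size_range_mb[2])
  n_sal <- round(n * spec$salmonid_fraction)
  sal <- sort(sample.int(n, n_sal))
  is_sal <- seq_len(n) %in% sal
  te_pct <- spec$te_intercept + spec$te_slope * size_mb +
    rnorm(n, 0, spec$noise_sd)
  te_pct <- pmin(pmax(te_pct, 1), 80)
  gc_bg <- spec$gc_intercept + spec$gc_slope * size_mb +
    rnorm(n, 0, spec$noise_sd)
  size_mb <- size_mb + ifelse(is_sal, spec$salmonid_size_boost_mb, 0)
  gc_bg <- gc_bg + ifelse(is_sal, spec$salmonid_gc_boost, 0)
  gc_bg <- pmin(pmax(gc_bg, 25), 65)
  gc_center <- spec$gc_intercept + spec$gc_slope * mean(spec$size_range_mb)
  targets <- adjust_group_targets(spec$group_profile, spec$class1_gc_offset)

  code <- sprintf("Ss%02d", seq_len(n))
  species_id <- sprintf("Simulatus species%02d", seq_len(n))

  libraries <- vector("list", n); genomes <- vector("list", n)
  truth_species <- vector("list", n); truth_groups <- vector("list", n)
  for (i in seq_len(n)) {
    shift <- spec$te_gc_coupling * (gc_bg[i] - gc_center)
    prof_i <- targets
    prof_i$gc_target <- pmin(pmax(prof_i$gc_target + shift, 5), 95)
    lib <- generate_te_library(prof_i, seed = species_seed(spec$seed, i, 1L),
                               length_range = spec$family_length_range)
    gen <- generate_genome(
      lib$library, size_bp = as.integer(round(size_mb[i] * 1e6)),
      gc_background = gc_bg[i], te_percent = te_pct[i],
      seed = species_seed(spec$seed, i, 2L),
      copy_mutation_rate = spec$copy_mutation_rate,
      n_gaps = spec$n_gaps, gap_length = spec$gap_length
    )
    libraries[[i]] <- lib$library
    genomes[[i]] <- gen$genome
    lib_counted <- sum(lib$truth$counted_bases)
    truth_species[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        species_id = species_id[i], short_code = code[i],
        salmonid = is_sal[i], size_mb = size_mb[i],
        gc_te_expected = sum(lib$truth$counted_bases * lib$truth$gc_target) /
          lib_counted,
        gc_te_realized = sum(lib$truth$gc_count) / lib_counted * 100,
        gc_te_shift = shift
      ),
      gen$truth
    )
    truth_groups[[i]] <- dplyr::mutate(
      dplyr::select(lib$truth, -"gc_count"),
      species_id = species_id[i], .before = 1
    )
    truth_groups[[i]]$gc_count <- lib$truth$gc_count
  }
  truth_species <- dplyr::bind_rows(truth_species)
  truth_groups <- dplyr::bind_rows(truth_groups)
  panel_groups <- truth_groups |>
    dplyr::group_by(.data$group, .data$te_class) |>
    dplyr::summarise(
      n_families = sum(.data$n_families),
      gc_expected_pooled = sum(.data$counted_bases * .data$gc_target) /
        sum(.data$counted_bases),
      sd_binomial = 100 * sqrt(
        sum(.data$counted_bases * (.data$gc_target / 100) *
              (1 - .data$gc_target / 100))
      ) / sum(.data$counted_bases),
      gc_realized_pooled = 100 * sum(.data$gc_count) / sum(.data$counted_bases),
      counted_bases = sum(.data$counted_bases),
      .groups = "drop"
    )

  species <- tibble::tibble(
    species_id = species_id,
    short_code = code,
    lineage_flags = purrr::map(is_sal, ~ if (.x) c("teleost", "salmonid")
                               else "teleost"),
    c_values_pg = purrr::map(size_mb, ~ .x / 978 * c(0.995, 1.005)),
    assembly_size_mb = size_mb,
    gc_genome = truth_species$gc_genome_realized,
    te_percent = 100 * truth_species$repeat_fraction_realized,
    gc_te = truth_species$gc_te_realized,
    gc_rep = truth_species$gc_rep_realized,
    gc_nonrep = truth_species$gc_nonrep_realized
  )

  out <- list(
    species = species, truth_species = truth_species,
    truth_groups = truth_groups, panel_groups = panel_groups,
    group_targets = targets, spec = spec
  )
  if (is.null(dir)) {
    out$libraries <- setNames(libraries, code)
    out$genomes <- setNames(genomes, code)
  } else {
    dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "te_libs"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_fasta(genomes[[i]], file.path(dir, "genomes",
                                          paste0(code[i], ".fa.gz")))
      lib_out <- libraries[[i]]
      lib_out$seq_id <- paste0(lib_out$name, "#", lib_out$superfamily_raw)
      write_fasta(lib_out, file.path(dir, "te_libs", paste0(code[i], ".fa")))
    }
    write_species_table(species, file.path(dir, "species_table.tsv"))
    write_tegc_tsv(truth_species, file.path(dir, "truth_species.tsv"))
    write_tegc_tsv(truth_groups, file.path(dir, "truth_groups.tsv"))
    write_tegc_tsv(panel_groups, file.path(dir, "truth_panel_groups.tsv"))
    out$paths <- list(
      dir = dir,
      genomes = file.path(dir, "genomes", paste0(code, ".fa.gz")),
      te_libs = file.path(dir, "te_libs", paste0(code, ".fa")),
      species_table = file.path(dir, "species_table.tsv")
    )
  }
  class(out) <- "te_panel"
  out
}
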