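test_that("parse_te_header normalises the name#Class/Superfamily dialect", {
  got <- parse_te_header(c(
    "Tc1-1_DR#DNA/TcMar-Tc1", "ERV1-3_LO#LTR/ERV1", "someRepeat",
    "hel1#RC/Helitron", "pen1#Penelope/Penelope", "cmc2#DNA/CMC-EnSpm",
    "sat#Satellite", "weird#Foo/Bar", "bare#DNA"
  ))
  expect_equal(got$name[1:2], c("Tc1-1_DR", "ERV1-3_LO"))
  expect_equal(got$te_class,
               c("II", "I", "unknown", "II", "I", "II", "non-TE", "unknown", "II"))
  expect_equal(got$group,
               c("TcMar", "LTR", "Unknown", "Helitron", "Penelope", "CMC",
                 "Satellite", "Unknown", "Unknown"))
  expect_equal(got$superfamily_raw[1], "DNA/TcMar-Tc1")
  expect_equal(got$superfamily_raw[3], "")
})

test_that("classification is a pure function of the mapping table", {
  headers <- c("a#DNA/hAT-Ac", "b#LINE/L1", "c#Simple_repeat", "d#Mystery")
  base <- parse_te_header(headers)
  permuted <- default_te_classes()[sample(16), ]
  expect_equal(parse_te_header(headers, class_map = permuted), base)
  # a modified table changes the assignment
  custom <- default_te_classes()
  custom$te_class[custom$prefix == "RC"] <- "I"
  expect_equal(parse_te_header("h#RC/Helitron", class_map = custom)$te_class, "I")
})

test_that("load_te_library composes FASTA reading with header parsing", {
  path <- write_temp_fasta(c(
    ">fam1#DNA/TcMar-Tc1", "AATT",
    ">fam2#DNA/hAT-Ac", "GGCC",
    ">fam3#LTR/Gypsy", "GGGG",
    ">fam4#Simple_repeat", "ATAT",
    ">fam5#LINE/L2"
  ))
  lib <- load_te_library(path)
  expect_equal(lib$te_class, c("II", "II", "I", "non-TE", "I"))
  expect_equal(lib$length, c(4L, 4L, 4L, 4L, 0L))
  # empty library file -> empty collection
  expect_equal(nrow(load_te_library(write_temp_fasta(character(0)))), 0L)
  # the zero-length record is retained but never pooled
  prof <- species_gc_te(lib)
  expect_equal(prof$n_families, 3L)
})

test_that("species_gc_te pools each consensus once, by class and group", {
  lib <- tibble::tibble(
    name = c("f1", "f2"), te_class = c("II", "I"),
    group = c("TcMar", "LTR"), superfamily_raw = c("DNA/TcMar", "LTR/Gypsy"),
    length = c(4L, 4L), residues = c("AAAA", "GGGG")
  )
  prof <- species_gc_te(lib)
  expect_equal(prof$gc_te_overall, 50)
  expect_equal(prof$gc_class1, 100)
  expect_equal(prof$gc_class2, 0)
  # single family: overall GC equals the family GC
  one <- species_gc_te(lib[2, ])
  expect_equal(one$gc_te_overall, 100)
  # non-TE and unknown handling: unknown joins the overall pool only
  lib2 <- dplyr::bind_rows(lib, tibble::tibble(
    name = c("sat", "u"), te_class = c("non-TE", "unknown"),
    group = c("Satellite", "Unknown"), superfamily_raw = c("Satellite", ""),
    length = c(8L, 4L), residues = c("GGGGGGGG", "GGCC")
  ))
  prof2 <- species_gc_te(lib2)
  expect_equal(prof2$gc_class1, 100)   # untouched by non-TE / unknown entries
  expect_equal(prof2$gc_class2, 0)
  # pooled over I + II + unknown: (4 + 0 + 4) GC of 12 counted bases
  expect_equal(prof2$gc_te_overall, 100 * 8 / 12)
})

test_that("pooled consensus GC matches a brute-force concatenation tally", {
  withr::local_seed(81)
  groups <- c("TcMar", "hAT", "LTR", "LINE")
  lib <- tibble::tibble(
    name = sprintf("f%d", 1:50),
    te_class = rep(c("II", "II", "I", "I"), length.out = 50),
    group = rep(groups, length.out = 50),
    superfamily_raw = "x",
    residues = vapply(sample(50:400, 50, replace = TRUE), random_acgt_seq, "")
  )
  lib$length <- nchar(lib$residues)
  prof <- species_gc_te(lib)
  expect_equal(prof$gc_te_overall,
               oracle_gc(paste(lib$residues, collapse = "")))
  # invariant under record reordering
  expect_equal(species_gc_te(lib[sample(50), ])$gc_te_overall,
               prof$gc_te_overall)
  # overall GC lies within the per-group range
  per_group <- prof$per_group[[1]]
  expect_gte(prof$gc_te_overall, min(per_group$gc_percent))
  expect_lte(prof$gc_te_overall, max(per_group$gc_percent))
})

test_that("empty or non-countable libraries are flagged, not fatal", {
  empty <- tibble::tibble(name = "s", te_class = "non-TE", group = "Satellite",
                          superfamily_raw = "Satellite", length = 4L,
                          residues = "ACGT")
  expect_warning(prof <- species_gc_te(empty),
                 class = "tegc_empty_library_warning")
  expect_true(is.na(prof$gc_te_overall))
  expect_warning(expect_true(is.na(class_contrast(prof))),
                 class = "tegc_undefined_contrast_warning")
})

test_that("cross-species pooling reports both aggregation conventions", {
  mk <- function(id, gc_count, counted) {
    structure(tibble::tibble(
      species_id = id, n_families = 1L,
      gc_te_overall = 100 * gc_count / counted,
      gc_class1 = NA_real_, gc_class2 = 100 * gc_count / counted,
      per_group = list(tibble::tibble(
        group = "TcMar", te_class = "II", n_families = 1L,
        counted_bases = counted, gc_count = gc_count,
        gc_percent = 100 * gc_count / counted
      ))
    ), class = c("te_profile", class(tibble::tibble())))
  }
  two <- dplyr::bind_rows(mk("sp1", 10L, 20L), mk("sp2", 30L, 80L))
  pooled <- pool_groups_across_species(two)
  expect_equal(pooled$gc_pooled, 40)              # (10+30)/(20+80)
  expect_equal(pooled$gc_mean_of_species, 43.75)  # mean(50, 37.5)
  expect_equal(pooled$n_species, 2L)
  # single species: the two conventions coincide
  one <- pool_groups_across_species(mk("solo", 10L, 20L))
  expect_equal(one$gc_pooled, one$gc_mean_of_species)
  # equal counted-base totals per species: conventions agree exactly
  eq <- dplyr::bind_rows(mk("e1", 12L, 40L), mk("e2", 28L, 40L))
  eq_pooled <- pool_groups_across_species(eq)
  expect_equal(eq_pooled$gc_pooled, eq_pooled$gc_mean_of_species)
  # pooled value is bracketed by the per-species extremes
  expect_gte(pooled$gc_pooled, 37.5)
  expect_lte(pooled$gc_pooled, 50)
})

test_that("class_contrast reports the signed Class I minus Class II difference", {
  expect_equal(class_contrast(tibble::tibble(gc_class1 = 45.6, gc_class2 = 40.1)),
               5.5)
  expect_equal(class_contrast(tibble::tibble(gc_class1 = 42, gc_class2 = 42)), 0)
})

test_that("tidy and glance summarise te_profile collections", {
  withr::local_seed(82)
  libs <- generate_te_library(default_group_profile(), seed = 5,
                              length_range = c(100L, 300L))
  prof <- species_gc_te(libs$library, species_id = "sp1")
  td <- tidy(prof)
  expect_true(all(c("species_id", "group", "gc_percent") %in% names(td)))
  expect_equal(nrow(td), 6L)
  gl <- glance(prof)
  expect_equal(gl$n_species, 1L)
  expect_equal(gl$gc_te_overall, prof$gc_te_overall)
})
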