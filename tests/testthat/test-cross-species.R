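make_table <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(species_table_lines(rows), path)
  path
}

test_that("load_species_table types cells and treats blanks as missing", {
  tab <- load_species_table(make_table(c(
    "Danio rerio\tDre\tteleost\t1.75;1.80\t1345\t36.8\t52.2\t39.6\t36.1\t37.0",
    "Salmo salar\tSsa\tteleost|salmonid\t3.27\t2967\t43.5\t.\t.\t.\t.",
    "Petromyzon marinus\tPma\toutgroup\t\t.\t.\t.\t45.9\t.\t."
  )))
  expect_equal(tab$c_values_pg[[1]], c(1.75, 1.80))
  expect_equal(tab$lineage_flags[[2]], c("teleost", "salmonid"))
  expect_equal(tab$c_values_pg[[3]], numeric(0))
  expect_true(is.na(tab$gc_te[2]))          # missing, never zero
  expect_equal(tab$gc_te[3], 45.9)
})

test_that("load_species_table rejects malformed records with line numbers", {
  expect_error(
    load_species_table(make_table(
      "Bad fish\tBad\tteleost\t-1.2\t.\t.\t.\t.\t.\t."
    )),
    regexp = "line 2", class = "tegc_format_error"
  )
  expect_error(
    load_species_table(make_table(
      "Bad fish\tBad\tteleost\t1.2\tabc\t.\t.\t.\t.\t."
    )),
    regexp = "assembly_size_mb", class = "tegc_format_error"
  )
  extra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_id\tmystery", "Fish a\tx"), extra)
  expect_warning(load_species_table(extra), regexp = "mystery")
})

test_that("mean_c_value averages repeated measurements", {
  expect_equal(mean_c_value(list(c(1.0, 1.4), 2.0, numeric(0))),
               c(1.2, 2.0, NA_real_))
})

test_that("filters exclude deterministically and log every exclusion", {
  tab <- load_species_table(make_table(c(
    sprintf("Teleostei sp%02d\tT%02d\tteleost\t1.0\t900\t40\t20\t42\t39\t41",
            1:5, 1:5),
    sprintf("Salmo sp%02d\tS%02d\tteleost|salmonid\t3.0\t2800\t44\t30\t.\t.\t.",
            1:8, 1:8),
    "Lepisosteus oculatus\tLoc\tnon-teleost-ray-finned\t1.4\t946\t40.4\t15\t46\t41\t40"
  )))
  filtered <- apply_filters(tab, filters = "exclude_salmonids")
  log <- exclusion_log(filtered)
  expect_equal(nrow(filtered), 6L)
  expect_equal(nrow(log), 8L)
  expect_true(all(grepl("^Salmo", log$species_id)))
  expect_equal(nrow(filtered) + nrow(log), nrow(tab))
  # no filter -> identity with empty log
  ident <- apply_filters(tab)
  expect_equal(nrow(ident), nrow(tab))
  expect_equal(nrow(exclusion_log(ident)), 0L)
  # missing-variable requirement reduces n and is logged per variable
  need <- apply_filters(tab, require_vars = "gc_te")
  expect_equal(nrow(need), 6L)
  expect_equal(nrow(exclusion_log(need)) + nrow(need), nrow(tab))
  # teleost restriction
  tel <- apply_filters(tab, filters = "teleosts_only")
  expect_false("Lepisosteus oculatus" %in% tel$species_id)
  expect_error(apply_filters(tab, filters = "drop_sharks"),
               class = "tegc_config_error")
})

test_that("correlate matches exact-linearity, antisymmetry and rank oracles", {
  d <- tibble::tibble(species_id = letters[1:3], x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(correlate(d, "x", "y", method = "pearson")$coefficient, 1)
  withr::local_seed(91)
  r <- tibble::tibble(species_id = letters[1:7], x = rnorm(7), y = rnorm(7))
  for (m in c("pearson", "spearman")) {
    plus <- correlate(r, "x", "y", method = m)
    minus <- correlate(dplyr::mutate(r, y = -y), "x", "y", method = m)
    expect_equal(minus$coefficient, -plus$coefficient)
  }
  sp <- correlate(r, "x", "y", method = "spearman")
  expect_equal(sp$coefficient, oracle_spearman(r$x, r$y))
  expect_equal(sp$p_value, oracle_spearman_perm_p(r$x, r$y))
  pe <- correlate(r, "x", "y", method = "pearson")
  expect_equal(pe$coefficient, oracle_pearson(r$x, r$y))
})

test_that("correlate is invariant under reordering and positive rescaling", {
  withr::local_seed(92)
  r <- tibble::tibble(species_id = letters[1:10], x = rnorm(10), y = rnorm(10))
  perm <- sample(10)
  for (m in c("pearson", "spearman")) {
    expect_equal(correlate(r[perm, ], "x", "y", method = m)$coefficient,
                 correlate(r, "x", "y", method = m)$coefficient)
  }
  scaled <- dplyr::mutate(r, x = 3.7 * x + 11)
  expect_equal(correlate(scaled, "x", "y", method = "pearson")$coefficient,
               correlate(r, "x", "y", method = "pearson")$coefficient)
})

test_that("correlate enforces missing-data and degenerate-variance contracts", {
  d <- tibble::tibble(species_id = letters[1:5], x = c(1, 2, 3, NA, 5),
                      y = c(2, 1, NA, 4, 3))
  ct <- correlate(d, "x", "y")
  expect_equal(ct$n, 3L)
  expect_setequal(ct$excluded[[1]], c("c", "d"))
  expect_error(correlate(d[1:2, ], "x", "y"),
               class = "tegc_insufficient_data_error")
  flat <- tibble::tibble(species_id = letters[1:4], x = 1:4, y = rep(2, 4))
  expect_warning(res <- correlate(flat, "x", "y"),
                 class = "tegc_zero_variance_warning")
  expect_true(is.na(res$coefficient))
})

suite_fixture <- function() {
  withr::local_seed(93, .local_envir = parent.frame())
  n <- 20
  size <- runif(n, 0.8, 3.2)
  sal <- c(rep(FALSE, 16), rep(TRUE, 4))
  gc <- 48 - 3 * size + rnorm(n, 0, 0.6) + ifelse(sal, 5, 0)
  tibble::tibble(
    species_id = sprintf("Fish sp%02d", 1:n),
    short_code = sprintf("F%02d", 1:n),
    lineage_flags = purrr::map(sal, ~ if (.x) c("teleost", "salmonid") else "teleost"),
    c_values_pg = purrr::map(size + ifelse(sal, 1.5, 0), ~ .x / 978),
    assembly_size_mb = size + ifelse(sal, 1.5, 0),
    gc_genome = gc,
    te_percent = 10 + 8 * size + rnorm(n, 0, 0.8),
    gc_te = gc + 4 + rnorm(n, 0, 0.4),
    gc_rep = gc + 2 + rnorm(n, 0, 0.3),
    gc_nonrep = gc + rnorm(n, 0, 0.3)
  )
}

test_that("analysis_suite runs every analysis with provenance and sign table", {
  tab <- suite_fixture()
  suite <- analysis_suite(tab)
  expect_setequal(unique(suite$analysis),
                  c("size_te", "size_gc_excl_salmonids", "size_gc_incl_salmonids",
                    "asmsize_gc", "gcte_gcg", "gcrep_gcnonrep"))
  expect_setequal(unique(suite$method), c("spearman", "pearson"))
  excl <- dplyr::filter(suite, analysis == "size_gc_excl_salmonids",
                        method == "spearman")
  expect_equal(excl$n, 16L)
  expect_equal(excl$filter, "exclude_salmonids")
  expect_lt(excl$coefficient, 0)
  sign_table <- attr(suite, "sign_table")
  expect_equal(nrow(sign_table), 20L)
  expect_true(all(!sign_table$te_gc_poorer))   # gc_te planted above gc_genome
  # tidy/glance views
  expect_false("excluded" %in% names(tidy(suite)))
  expect_equal(glance(suite)$n_analyses, 6L)
})

test_that("analyses without data are skipped with a reason, never silently", {
  tab <- dplyr::select(suite_fixture(), -"gc_rep", -"gc_nonrep")
  expect_message(suite <- analysis_suite(tab), regexp = "gcrep_gcnonrep")
  skipped <- attr(suite, "skipped")
  expect_true("gcrep_gcnonrep" %in% skipped$analysis)
  expect_false("gcrep_gcnonrep" %in% suite$analysis)
})

test_that("analysis_suite output is identical across repeated runs", {
  tab <- suite_fixture()
  s1 <- analysis_suite(tab)
  s2 <- analysis_suite(tab)
  expect_identical(tidy(s1), tidy(s2))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_tegc_tsv(tidy(s1), p1)
  write_tegc_tsv(tidy(s2), p2)
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
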