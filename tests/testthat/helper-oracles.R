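# Independent oracles: deliberately naive per-character / closed-form
# implementations, kept free of any package internals they are used to check.

iupac_alphabet <- c(
  "A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
  "a", "c", "g", "t", "u", "n", "r", "y", "s", "w", "k", "m", "-", "."
)

random_iupac_seq <- function(len, alphabet = iupac_alphabet) {
  if (len == 0) return("")
  # weight plain bases heavily so GC fractions are usually defined
  w <- ifelse(alphabet %in% c("A", "C", "G", "T", "a", "c", "g", "t"), 10, 1)
  paste(sample(alphabet, len, replace = TRUE, prob = w), collapse = "")
}

random_acgt_seq <- function(len, lower_frac = 0.5) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  lower <- runif(len) < lower_frac
  base[lower] <- tolower(base[lower])
  paste(base, collapse = "")
}

# per-character tally, one character at a time
oracle_counts <- function(seqs) {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  cnt <- function(set) sum(chars %in% set)
  list(
    a_upper = cnt("A"), c_upper = cnt("C"), g_upper = cnt("G"),
    t_upper = cnt(c("T", "U")),
    a_lower = cnt("a"), c_lower = cnt("c"), g_lower = cnt("g"),
    t_lower = cnt(c("t", "u")),
    n_count = cnt(c("N", "n")),
    other_count = sum(!chars %in% c("A", "C", "G", "T", "U", "a", "c", "g",
                                    "t", "u", "N", "n")),
    total_length = length(chars)
  )
}

# GC% over a case fraction, straight from the per-character tally
oracle_gc <- function(seqs, fraction = "all") {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  sel <- switch(fraction,
    all = chars %in% c("A", "C", "G", "T", "U", "a", "c", "g", "t", "u"),
    masked_only = chars %in% c("a", "c", "g", "t", "u"),
    unmasked_only = chars %in% c("A", "C", "G", "T", "U")
  )
  kept <- chars[sel]
  if (length(kept) == 0) return(NA_real_)
  100 * sum(kept %in% c("G", "C", "g", "c")) / length(kept)
}

reverse_complement <- function(seq) {
  comp <- chartr("ACGTUacgtuRYKMrykm", "TGCAAtgcaaYRMKyrmk", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# closed-form Pearson coefficient from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman as Pearson applied to mid-ranks
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  smaller <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[smaller], nrow(smaller)))
  }))
}

# two-sided permutation p-value for Spearman's rho by full enumeration
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  r_obs <- abs(cor(x, y, method = "spearman"))
  perm <- all_permutations(n)
  r_all <- apply(perm, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(r_all) >= r_obs - 1e-12)
}

write_temp_fasta <- function(lines, ext = ".fa") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal well-formed species table as TSV text
species_table_lines <- function(rows) {
  header <- paste(c("species_id", "short_code", "lineage_flags", "c_values_pg",
                    "assembly_size_mb", "gc_genome", "te_percent", "gc_te",
                    "gc_rep", "gc_nonrep"), collapse = "\t")
  c(header, rows)
}

tiny_panel_spec <- function(seed = 11, n_species = 6) {
  panel_spec(
    n_species = n_species, seed = seed, size_range_mb = c(0.04, 0.12),
    family_length_range = c(200L, 800L), n_gaps = 1L, gap_length = 100L,
    salmonid_fraction = 1 / 3
  )
}
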