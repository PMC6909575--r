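#' Read a FASTA file into a tibble
#'
#' Reads a (possibly gzip-compressed) FASTA file and returns one row per
#' record. Residue case is preserved exactly as found in the file: in
#' soft-masked assemblies (e.g. Ensembl "sm" dumps) lowercase residues mark
#' RepeatMasker-detected repeats, so case carries meaning and is never
#' normalised. Line wrapping and trailing whitespace are removed.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return A tibble with columns `seq_id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, `""` if absent) and
#'   `residues` (the concatenated sequence, case preserved; may be empty).
#'   An empty file yields a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 toy", "aattGG", "CC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "tegc_input_error")
  }
  first <- fasta_first_nonblank(path)
  if (is.null(first)) {
    return(tibble::tibble(
      seq_id = character(), description = character(), residues = character()
    ))
  }
  if (!startsWith(first, ">")) {
    abort(
      paste0("not FASTA: first non-blank line lacks '>' in ", path),
      class = "tegc_format_error"
    )
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  tibble::tibble(
    seq_id = sub("\\s.*$", "", headers),
    description = ifelse(
      grepl("\\s", headers), sub("^\\S+\\s+", "", headers), ""
    ),
    residues = gsub("\\s+", "", unname(as.character(set)))
  )
}

fasta_first_nonblank <- function(path) {
  con <- gzfile(path, "rt")  # gzfile reads plain text transparently too
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NULL)
    if (nzchar(trimws(line))) return(line)
  }
}

#' Write sequences to a FASTA file
#'
#' Companion writer to [read_fasta()]: writes one record per row, preserving
#' residue case, wrapping sequence lines at a fixed width. Output uses LF line
#' endings regardless of platform so that identical inputs produce
#' byte-identical files. Paths ending in `.gz` are gzip-compressed.
#'
#' @param seqs A data frame with columns `seq_id`, `residues` and optionally
#'   `description`.
#' @param path Output path; compressed when it ends in `.gz`.
#' @param width Residues per sequence line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("seq_id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else
    rep("", nrow(seqs))
  header <- ifelse(
    is.na(desc) | !nzchar(desc),
    paste0(">", seqs$seq_id),
    paste0(">", seqs$seq_id, " ", desc)
  )
  chunks <- purrr::map2(header, seqs$residues, function(h, s) {
    n <- nchar(s)
    if (n == 0L) return(h)
    starts <- seq.int(1L, n, by = width)
    c(h, substring(s, starts, pmin(starts + width - 1L, n)))
  })
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(unlist(chunks), con, sep = "\n")
  invisible(path)
}
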