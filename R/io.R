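## File I/O: FASTA/Newick/TSV/JSON wrappers and atomic writes.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file (amino acid or nucleotide).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path (written atomically).
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  lines <- character(0)
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), width)
    lines <- c(lines, paste0(">", nm[i]),
               substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }
  atomic_writeLines(lines, path)
}

atomic_writeLines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a data frame as a TSV file (atomically)
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

## JSON report writer (atomic)
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a profile matrix as TSV
#'
#' One row per profile column, 20 score columns plus effective counts.
#' @param profile A `profile_matrix`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(column = seq_len(profile$length),
                   profile$scores, eff_count = profile$eff_counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a profile TSV back into a `profile_matrix`
#' @param path Path written by [write_profile_tsv()].
#' @param background Background vector (default uniform).
#' @param alpha Pseudocount weight annotation.
#' @param family Family id.
#' @return A `profile_matrix`.
#' @export
read_profile_tsv <- function(path, background = uniform_background(),
                             alpha = 1, family = NA_character_) {
  df <- read_tsv(path)
  scores <- as.matrix(df[, AA_ALPHABET])
  dimnames(scores) <- list(NULL, AA_ALPHABET)
  structure(list(family = family, length = nrow(df), scores = scores,
                 eff_counts = df$eff_count, background = background,
                 alpha = alpha, kept_columns = seq_len(nrow(df))),
            class = "profile_matrix")
}
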