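# Small shared helpers: sequence string manipulation and FASTQ/FASTA io.
# Sequences are held as plain uppercase character strings over ACGTN;
# Biostrings is used at the file-format boundary.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A, C, G, T, N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Split sequences into per-position character matrix rows
#' @noRd
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)
}

#' Extract single bases at given 1-based positions of one sequence
#' @noRd
bases_at <- function(seq, pos) {
  stringi::stri_sub(seq, from = pos, to = pos)
}

#' Replace single characters at given 1-based positions of one sequence
#' @noRd
sub_positions <- function(seq, pos, repl) {
  if (!length(pos)) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- repl
  paste(v, collapse = "")
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' uppercase character strings keyed by the full header line.
#'
#' @param path FASTA file (gzip allowed).
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write a named character vector to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file, plain or gzip.
#' @return named character vector of read sequences (names from the
#'   `@` header lines, first whitespace-delimited token).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write reads to FASTQ
#'
#' Emits a constant quality line (the simulator's error model is encoded
#' in the base calls, not in qualities).
#'
#' @param seqs named character vector of read sequences.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("F", n), character(1))
  rec <- paste0("@", names(seqs), "\n", seqs, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Deterministic sub-seed derivation
#'
#' Derives a child seed from a parent seed and a stage label so that every
#' stage of a run draws from an independent, reproducible stream.  Kept
#' within the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
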