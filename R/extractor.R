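# Read extraction: permissive pre-filter retaining read pairs with at
# least one mate aligning to the target-locus haplotype references.
# Filtration is recall-critical, so the mismatch cap is looser than in
# the genotyping alignments.

#' Extract target-locus read pairs
#'
#' Retains every read pair for which at least one mate aligns to any of
#' the haplotype references at the permissive extractor threshold.
#' Pair integrity is preserved: mates are kept or dropped together.
#'
#' @param fq1,fq2 paths to the paired FASTQ files (gzip allowed), or
#'   named character vectors of read sequences.
#' @param haplotype_refs named character vector of haplotype reference
#'   sequences (or a FASTA path).
#' @param max_mm extractor mismatch cap (default 10 per 150 bp read).
#' @param out1,out2 optional output FASTQ paths for the retained pairs.
#' @return list with `r1`, `r2` (retained reads), and `counts`
#'   (`n_pairs`, `n_retained`, `retention`).
#' @export
extract_reads <- function(fq1, fq2, haplotype_refs, max_mm = 10L,
                          out1 = NULL, out2 = NULL) {
  if (is.character(haplotype_refs) && length(haplotype_refs) == 1L &&
      file.exists(haplotype_refs)) {
    haplotype_refs <- read_fasta(haplotype_refs)
  }
  stopifnot(length(haplotype_refs) > 0L)
  r1 <- if (length(fq1) == 1L && file.exists(fq1)) read_fastq(fq1) else fq1
  r2 <- if (length(fq2) == 1L && file.exists(fq2)) read_fastq(fq2) else fq2
  key1 <- sub("/1$", "", names(r1))
  key2 <- sub("/2$", "", names(r2))
  if (length(r1) != length(r2) || !identical(key1, key2)) {
    stop("mate files do not pair up record-for-record")
  }
  if (!length(r1)) {
    return(list(r1 = r1, r2 = r2,
                counts = c(n_pairs = 0L, n_retained = 0L,
                           retention = NaN)))
  }
  hit1 <- align_reads(r1, haplotype_refs, mode = "best", max_mm = max_mm)
  hit2 <- align_reads(r2, haplotype_refs, mode = "best", max_mm = max_mm)
  keep <- key1 %in% sub("/1$", "", unique(hit1$read)) |
          key2 %in% sub("/2$", "", unique(hit2$read))
  out <- list(r1 = r1[keep], r2 = r2[keep],
              counts = c(n_pairs = length(keep),
                         n_retained = sum(keep),
                         retention = mean(keep)))
  if (!is.null(out1)) write_fastq(out$r1, out1)
  if (!is.null(out2)) write_fastq(out$r2, out2)
  out
}
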