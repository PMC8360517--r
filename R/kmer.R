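# Shared k-mer homology analysis: quantifies sequence identity between
# genes as the proportion of each gene's distinct k-mers that also occur
# in other genes, at k typical of short-read lengths (50/150/250).

#' Distinct k-mers of a set of allele sequences
#'
#' Union of all length-`k` substrings over the given sequences, on the
#' given strand only (family alleles are co-oriented).  Windows containing
#' `N` are excluded: unknown bases cannot certify identity.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length (>= 1).
#' @return character vector of distinct k-mers.
#' @export
distinct_kmers <- function(seqs, k) {
  stopifnot(k >= 1L)
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) {
    warning("all sequences shorter than k = ", k)
    return(character())
  }
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    stringi::stri_sub(s, from = seq_len(n), length = k)
  }), use.names = FALSE)
  out <- unique(out)
  out[!stringi::stri_detect_fixed(out, "N")]
}

#' Pairwise shared k-mer matrix for a gene family
#'
#' For every gene, computes its distinct k-mer count, the pairwise counts
#' shared with each other gene, the aggregate count shared with the union
#' of all other genes, and the corresponding proportions (shared divided
#' by the gene's own distinct k-mer total, so the matrix of proportions
#' is not symmetric even though shared counts are).
#'
#' @param db an `AlleleDatabase`, or a named list of character vectors of
#'   sequences (one element per gene).
#' @param k k-mer length.
#' @return a `KmerSharingMatrix`: list with `k`, `totals`, `shared`
#'   (gene x gene count matrix), `shared_any` (aggregate counts),
#'   `proportion` (pairwise), `proportion_any` (aggregate).
#' @export
sharing_matrix <- function(db, k) {
  by_gene <- if (inherits(db, "AlleleDatabase")) {
    split(db$alleles$seq, db$alleles$gene)
  } else {
    db
  }
  if (length(by_gene) < 2L) stop("need at least two genes")
  genes <- sort(names(by_gene))
  kmers <- lapply(by_gene[genes], distinct_kmers, k = k)
  totals <- lengths(kmers)
  shared <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      shared[i, j] <- length(intersect(kmers[[i]], kmers[[j]]))
    }
  }
  shared_any <- vapply(seq_along(genes), function(i) {
    others <- unique(unlist(kmers[-i], use.names = FALSE))
    length(intersect(kmers[[i]], others))
  }, integer(1))
  names(shared_any) <- genes
  structure(list(
    k = k, totals = totals, shared = shared, shared_any = shared_any,
    proportion = shared / pmax(totals, 1L),
    proportion_any = shared_any / pmax(totals, 1L)
  ), class = "KmerSharingMatrix")
}

#' @export
print.KmerSharingMatrix <- function(x, ...) {
  cat(sprintf("KmerSharingMatrix (k = %d)\n", x$k))
  print(round(x$proportion_any, 3))
  invisible(x)
}

#' Long-format k-mer sharing table
#'
#' @param x a `KmerSharingMatrix`.
#' @return data.frame with columns `gene_a`, `gene_b`, `k`, `shared`,
#'   `total_a`, `proportion_a`.
#' @export
sharing_table <- function(x) {
  genes <- rownames(x$shared)
  grid <- expand.grid(gene_a = genes, gene_b = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$gene_a != grid$gene_b, ]
  data.frame(grid, k = x$k,
             shared = x$shared[cbind(grid$gene_a, grid$gene_b)],
             total_a = unname(x$totals[grid$gene_a]),
             proportion_a = x$proportion[cbind(grid$gene_a, grid$gene_b)],
             row.names = NULL)
}
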