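# Batch copy-number determination from unique-read depth ratios.
# Per sample and gene, the count of reads aligning uniquely to that
# gene/major allelic group is divided by the framework gene's unique
# count; across a batch the ratios cluster by copy number, and cut
# points between clusters convert ratios into integer copies.

#' Unique-read ratio matrix for a batch
#'
#' @param counts samples x groups matrix (or data.frame) of unique-read
#'   counts.
#' @param framework framework group label (the normalizer, assumed
#'   present at two copies in every sample).
#' @return a `CopyRatioMatrix`: list with `ratios` (samples x groups),
#'   `framework`, and `excluded` (samples with zero framework count).
#' @export
ratio_matrix <- function(counts, framework) {
  counts <- as.matrix(counts)
  if (!framework %in% colnames(counts)) {
    stop("framework group ", framework, " absent from count matrix")
  }
  fw <- counts[, framework]
  excluded <- rownames(counts)[fw == 0]
  if (length(excluded)) {
    warning("excluding sample(s) with zero framework count: ",
            paste(excluded, collapse = ", "))
  }
  keep <- fw > 0
  ratios <- counts[keep, , drop = FALSE] / fw[keep]
  structure(list(ratios = ratios, framework = framework,
                 excluded = excluded), class = "CopyRatioMatrix")
}

#' Automatic copy-group thresholds for one gene
#'
#' Exploits the integer structure of copy number directly: across a
#' batch, a gene's ratios sit near `s * copy` for an unknown per-copy
#' spacing `s` (0.5 for a gene whose sequence is essentially all
#' unique, smaller for genes that share most of their sequence with
#' neighbors and retain only a sliver of unique k-mers).  The spacing
#' is fitted by grid search over candidate spacings derived from the
#' observed ratios, each candidate scored by the spacing-normalized
#' squared residual of the implied integer assignment, with ties broken
#' toward the larger spacing and a least-squares refinement of the
#' winner.  A ratio below
#' half the spacing is copy 0.  When the batch realizes only a single
#' positive copy level the fit is degenerate (`s` and `s/2` explain the
#' data equally well); the framework-relative spacing of 0.5 per copy
#' is then assumed and the gene flagged for review.  Cut points sit at
#' the half-copy multiples of the fitted spacing.
#'
#' @param ratios numeric vector of per-sample ratios for one gene.
#' @param max_copy largest copy number considered (default 4).
#' @param min_batch minimum batch size (default 10).
#' @param min_spacing smallest admissible per-copy spacing (default
#'   0.02): a gene whose per-copy unique-read signal is below 2% of the
#'   framework gene's is beyond calling.
#' @return a `CopyThresholds`: list with `cuts` (ordered cut points; a
#'   ratio maps to the copy indexed by the number of cuts at or below
#'   it), `copies` (assigned copy per input ratio), `spacing`,
#'   `separability` (1 = ratios at cluster centers, 0 = a ratio on a
#'   copy boundary), `flagged`, `provenance`.
#' @export
auto_thresholds <- function(ratios, max_copy = 4L, min_batch = 10L,
                            min_spacing = 0.02) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < min_batch) {
    stop("need at least ", min_batch, " samples for automatic thresholds")
  }
  done <- function(cuts, copies, spacing, separability, flagged) {
    structure(list(cuts = cuts, copies = copies, spacing = spacing,
                   separability = separability, flagged = flagged,
                   provenance = "auto"),
              class = "CopyThresholds")
  }
  pos <- ratios[ratios > min_spacing / 2]
  if (!length(pos)) { # gene absent from the whole batch
    return(done(numeric(), rep(0L, length(ratios)), NA_real_, 1, FALSE))
  }
  cand <- unique(as.vector(outer(pos, seq_len(max_copy), `/`)))
  cand <- sort(cand[cand >= max(min_spacing, max(ratios) /
                                              (max_copy + 0.49))])
  assign_for <- function(s) pmin(as.integer(round(ratios / s)), max_copy)
  # residuals are normalized by the spacing: a finer grid always shrinks
  # absolute residuals, so the unnormalized cost would drift toward
  # half-spacings (doubling every call)
  cost_for <- function(s) sum(((ratios - assign_for(s) * s) / s)^2)
  costs <- vapply(cand, cost_for, numeric(1))
  best <- min(costs)
  s <- max(cand[costs <= best * (1 + 1e-9) + 1e-12])
  copies <- assign_for(s)
  # least-squares refinement of the spacing given the assignment
  if (any(copies > 0L)) {
    s <- sum(ratios * copies) / sum(copies^2)
    copies <- assign_for(s)
  }
  flagged <- FALSE
  levels_pos <- sort(unique(copies[copies > 0L]))
  if (length(levels_pos) == 1L) {
    # degenerate: no copy contrast; assume framework-relative spacing
    flagged <- TRUE
    cp <- max(1L, min(max_copy, as.integer(round(mean(pos) / 0.5))))
    copies[copies > 0L] <- cp
    s <- mean(pos) / cp
  }
  resid <- abs(ratios - copies * s)
  separability <- max(0, 1 - 2 * max(resid) / s)
  if (separability < 0.3) flagged <- TRUE
  cuts <- (seq_len(max(copies)) - 0.5) * s
  done(cuts, copies, s, separability, flagged)
}

#' Manual copy thresholds
#'
#' @param cuts strictly increasing cut points.
#' @return a `CopyThresholds` with provenance `"manual"`.
#' @export
manual_thresholds <- function(cuts) {
  stopifnot(!is.unsorted(cuts, strictly = TRUE))
  structure(list(cuts = cuts, copies = seq_len(length(cuts) + 1L) - 1L,
                 separability = NA_real_, flagged = FALSE,
                 provenance = "manual"),
            class = "CopyThresholds")
}

#' Convert ratios to integer copies with given thresholds
#'
#' A ratio equal to a cut point is assigned to the higher interval.
#'
#' @param ratios numeric vector of ratios for one gene.
#' @param thresholds a `CopyThresholds`.
#' @return integer copy vector.
#' @export
call_copies <- function(ratios, thresholds) {
  if (!length(thresholds$cuts)) {
    return(rep(thresholds$copies[1L], length(ratios)))
  }
  vapply(ratios, function(r) sum(r >= thresholds$cuts), integer(1))
}

#' Batch copy calling over all genes
#'
#' Applies [auto_thresholds()] and [call_copies()] per gene; the
#' framework gene is assigned copy 2 throughout (it is the normalizer and
#' assumed always present).  Manual thresholds override the automatic
#' procedure for the genes they name.
#'
#' @param rm a `CopyRatioMatrix`.
#' @param max_copy copy cap (default 4).
#' @param overrides optional named list of `CopyThresholds` per gene.
#' @return list with `copies` (samples x groups integer matrix),
#'   `thresholds` (per-gene list) and `flagged` (gene labels needing
#'   review).
#' @export
batch_copy_calls <- function(rm, max_copy = 4L, overrides = list()) {
  stopifnot(inherits(rm, "CopyRatioMatrix"))
  genes <- colnames(rm$ratios)
  copies <- matrix(NA_integer_, nrow(rm$ratios), length(genes),
                   dimnames = dimnames(rm$ratios))
  thresholds <- list()
  for (g in genes) {
    if (g == rm$framework) {
      copies[, g] <- 2L
      next
    }
    th <- if (!is.null(overrides[[g]])) overrides[[g]]
          else auto_thresholds(rm$ratios[, g], max_copy = max_copy)
    thresholds[[g]] <- th
    copies[, g] <- call_copies(rm$ratios[, g], th)
  }
  flagged <- names(thresholds)[vapply(thresholds, `[[`, TRUE, "flagged")]
  list(copies = copies, thresholds = thresholds, flagged = flagged)
}

#' Derive a paired gene's copies from its partner
#'
#' For complementary allelic-group pairs occupying one locus (every
#' haplotype carries exactly one of the two), a well-separated partner
#' determines the other: `copy[gene_a] = total - copy[gene_b]`.
#'
#' @param copies samples x groups copy matrix.
#' @param gene_a gene to set.
#' @param gene_b gene already called.
#' @param total locus copy total (default 2).
#' @return updated copy matrix.
#' @export
paired_gene_fallback <- function(copies, gene_a, gene_b, total = 2L) {
  if (any(copies[, gene_b] > total)) {
    stop(gene_b, " copies exceed the locus total of ", total)
  }
  copies[, gene_a] <- total - copies[, gene_b]
  copies
}
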