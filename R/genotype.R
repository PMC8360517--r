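# Genotype determination: depth tables -> SNP tables -> mismatch scoring
# of allele combinations at 7-digit then 5-digit resolution.
#
# Two parameterizations are used by the workflow: the initial stage
# compares the imputed/extended sequences over all allele-differentiating
# positions with uncharacterized comparison bases counting as full
# mismatches; the final stage compares the unimputed sequences over
# exonic positions only, with uncharacterized bases counting as matches.

#' Scoring parameters for a genotyping stage
#'
#' @param stage `"initial"` or `"final"`.
#' @param ... overrides for individual parameters (`min_depth`,
#'   `het_ratio`, `hom_buffer`, `max_copy`, `uncharacterized_policy`,
#'   `position_scope`, `comparison_set`).
#' @return a `ScoringParams` list.
#' @export
scoring_params <- function(stage = c("initial", "final"), ...) {
  stage <- match.arg(stage)
  p <- if (stage == "initial") {
    list(stage = "initial", min_depth = 8L, het_ratio = 0.25,
         hom_buffer = 4L, max_copy = 3L,
         uncharacterized_policy = "mismatch",
         position_scope = "differentiating", comparison_set = "imputed")
  } else {
    list(stage = "final", min_depth = 20L, het_ratio = 0.25,
         hom_buffer = 1L, max_copy = 3L,
         uncharacterized_policy = "match",
         position_scope = "exonic", comparison_set = "unimputed")
  }
  over <- list(...)
  p[names(over)] <- over
  structure(p, class = "ScoringParams")
}

#' Call SNPs from a depth table
#'
#' Positions whose total depth passes the stage floor are retained; at
#' each, every variant whose depth is at least `het_ratio` times the
#' highest-depth variant is recorded (at most three, highest depth
#' first).  Zygosity is the number of recorded variants.
#'
#' @param depth a `DepthTable`.
#' @param params a `ScoringParams`.
#' @return a `SNPTable` data.frame: `pos` (frame position), `variants`
#'   (character, comma-joined), `depths` (comma-joined, same order),
#'   `zygosity`, `total`.
#' @export
call_snps <- function(depth, params) {
  counts <- depth$counts
  total <- colSums(counts)
  keep <- which(total >= params$min_depth)
  rows <- lapply(keep, function(j) {
    d <- counts[, j]
    mx <- max(d)
    v <- names(d)[d > 0 & d / mx >= params$het_ratio]
    v <- v[order(-d[v])]
    if (length(v) > 3L) v <- v[1:3]
    list(pos = j, variants = paste(v, collapse = ","),
         depths = paste(d[v], collapse = ","), zygosity = length(v),
         total = total[[j]])
  })
  out <- if (length(rows)) {
    data.frame(pos = vapply(rows, `[[`, 0L, "pos"),
               variants = vapply(rows, `[[`, "", "variants"),
               depths = vapply(rows, `[[`, "", "depths"),
               zygosity = vapply(rows, `[[`, 0L, "zygosity"),
               total = vapply(rows, `[[`, 0, "total"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(), variants = character(),
               depths = character(), zygosity = integer(),
               total = numeric())
  }
  class(out) <- c("SNPTable", class(out))
  out
}

#' Comparison base matrix for a group at given frame positions
#'
#' @param db extended `AlleleDatabase`.
#' @param frame output of [group_frame()].
#' @param positions frame positions.
#' @param comparison_set `"imputed"` (use imputed/extended bases) or
#'   `"unimputed"` (imputed and extended positions revert to `N`).
#' @return character matrix alleles x positions over `ACGTN` (`N` also
#'   where an allele has no base at a frame column).
#' @export
comparison_bases <- function(db, frame, positions,
                             comparison_set = "imputed") {
  alleles <- frame$alleles
  i <- match(alleles, db$alleles$allele)
  seqs <- db$alleles$seq[i]
  masks <- db$alleles$mask[i]
  out <- matrix("N", length(alleles), length(positions),
                dimnames = list(alleles, NULL))
  for (k in seq_along(alleles)) {
    map <- frame$maps[[alleles[k]]]
    inv <- rep(NA_integer_, frame$frame_len)
    inv[map] <- seq_along(map)
    ap <- inv[positions]
    ok <- !is.na(ap)
    b <- bases_at(seqs[k], ap[ok])
    if (comparison_set == "unimputed") {
      m <- bases_at(masks[k], ap[ok])
      b[m != "1"] <- "N"
    }
    out[k, ok] <- b
  }
  out
}

#' Positions used for scoring under a parameter set
#'
#' `"differentiating"` scope keeps SNP-table positions at which the
#' group's comparison alleles carry at least two distinct characterized
#' bases; `"exonic"` keeps positions inside exon features; `"all"`
#' keeps every SNP-table position.
#'
#' @param snps a `SNPTable`.
#' @param frame output of [group_frame()].
#' @param bases comparison matrix from [comparison_bases()] over
#'   `snps$pos`.
#' @param params a `ScoringParams`.
#' @return logical vector over `snps` rows.
#' @export
scoring_scope <- function(snps, frame, bases, params) {
  if (!nrow(snps)) return(logical())
  switch(params$position_scope,
    all = rep(TRUE, nrow(snps)),
    exonic = frame$exonic[snps$pos],
    differentiating = vapply(seq_len(nrow(snps)), function(j) {
      v <- unique(bases[, j])
      length(setdiff(v, "N")) >= 2L
    }, logical(1)),
    stop("unknown position scope: ", params$position_scope))
}

#' Homozygous mismatch score of one allele
#'
#' Number of homozygous called positions disagreeing with the allele;
#' uncharacterized allele bases count per the stage policy (full
#' mismatch initially, match at the final stage).
#'
#' @param called character vector of called bases at homozygous
#'   positions.
#' @param allele_bases the allele's bases at the same positions.
#' @param params a `ScoringParams`.
#' @return integer score.
#' @export
score_homozygous <- function(called, allele_bases, params) {
  if (!length(called)) return(0L)
  unchar <- allele_bases == "N"
  mm <- allele_bases != called & !unchar
  if (params$uncharacterized_policy == "mismatch") {
    sum(mm) + sum(unchar)
  } else {
    sum(mm)
  }
}

# index multisets of size k over n items, one per column, non-decreasing
multiset_indices <- function(n, k) {
  if (k == 1L) return(matrix(seq_len(n), nrow = 1L))
  cmb <- combn(n + k - 1L, k)
  cmb - (seq_len(k) - 1L)
}

# symmetric-difference mismatch count at one heterozygous position
het_position_score <- function(called, offered, policy) {
  n_unchar <- sum(offered == "N")
  real <- setdiff(unique(offered), "N")
  extra <- length(setdiff(real, called))
  missing <- length(setdiff(called, real))
  if (policy == "match") {
    # each uncharacterized member may stand in for one missing variant
    max(0L, missing - n_unchar) + extra
  } else {
    missing + extra + as.integer(n_unchar > 0L)
  }
}

#' Score all allele combinations for a group
#'
#' Enumerates multisets of the retained alleles of the size given by the
#' gene's copy number (capped at `max_copy`).  Per heterozygous
#' position, the combination's variant set is compared to the called
#' variants and mismatches counted as the symmetric-difference
#' cardinality; the homozygous score of each component allele is added.
#' The minimum-score combinations are returned.
#'
#' @param snps a `SNPTable` already restricted to the scoring scope.
#' @param bases comparison matrix over `snps$pos` (alleles x positions).
#' @param copy copy number (>= 1).
#' @param params a `ScoringParams`.
#' @param retain optional pre-filter of allele names to consider.
#' @return list with `combos` (list of sorted allele-name vectors, the
#'   best-scoring set), `score`, `hom_scores` (per retained allele) and
#'   `retained`.
#' @export
score_combinations <- function(snps, bases, copy, params,
                               retain = NULL) {
  alleles <- rownames(bases)
  if (!is.null(retain)) {
    bases <- bases[intersect(alleles, retain), , drop = FALSE]
    alleles <- rownames(bases)
  }
  stopifnot(length(alleles) > 0L, copy >= 1L)
  copy <- min(copy, params$max_copy)
  hom_idx <- which(snps$zygosity == 1L)
  het_idx <- which(snps$zygosity >= 2L)
  called_hom <- sub(",.*$", "", snps$variants[hom_idx])
  hom_scores <- vapply(alleles, function(a) {
    score_homozygous(called_hom, bases[a, hom_idx], params)
  }, integer(1))
  retained <- alleles[hom_scores <= min(hom_scores) + params$hom_buffer]
  het_called <- strsplit(snps$variants[het_idx], ",", fixed = TRUE)
  idx <- multiset_indices(length(retained), copy)
  scores <- vapply(seq_len(ncol(idx)), function(ci) {
    members <- retained[idx[, ci]]
    s <- sum(hom_scores[members])
    for (j in seq_along(het_idx)) {
      s <- s + het_position_score(
        het_called[[j]],
        bases[members, het_idx[j]],
        params$uncharacterized_policy)
    }
    s
  }, numeric(1))
  best <- which(scores == min(scores))
  combos <- lapply(best, function(ci) sort(retained[idx[, ci]]))
  combos <- unique(combos)
  list(combos = combos, score = min(scores), hom_scores = hom_scores,
       retained = retained)
}

#' Collapse allele names to a digit resolution
#'
#' Allele names follow `GENE*DDDDDDD`: the first three digits name the
#' protein-level group, five digits the synonymous-variant level, seven
#' the non-coding-variant level.
#'
#' @param alleles character vector of allele names.
#' @param digits 3, 5 or 7.
#' @return collapsed names.
#' @export
allele_resolution <- function(alleles, digits = 5L) {
  gene <- sub("\\*.*$", "", alleles)
  num <- sub("^[^*]*\\*", "", alleles)
  paste0(gene, "*", substr(num, 1L, digits))
}

#' Determine the genotype of one group from its depth table
#'
#' Runs SNP calling, scope filtering and combination scoring, then
#' resolves the typing: a unique best combination is a 7-digit call;
#' tied combinations that collapse to a single 5-digit multiset resolve
#' at 5-digit; otherwise the call is ambiguous.  At the final stage only
#' perfect (score 0) resolutions are accepted; any mismatch yields an
#' unresolved genotype.
#'
#' @param db extended `AlleleDatabase`.
#' @param group group label.
#' @param frame output of [group_frame()].
#' @param depth a `DepthTable` for the group.
#' @param copy called copy number.
#' @param params a `ScoringParams`.
#' @return a `GenotypeCall`: list with `group`, `copy`, `combos`,
#'   `score`, `resolution` (7, 5 or `NA`), `status` (`resolved`,
#'   `ambiguous`, `unresolved`, `null`, `no_reads`), `locked` (eligible
#'   for lock-in: unambiguous and perfect).
#' @export
genotype_group <- function(db, group, frame, depth, copy, params) {
  if (copy == 0L) {
    return(structure(list(group = group, copy = 0L, combos = list(),
                          score = 0L, resolution = NA_integer_,
                          status = "null", locked = FALSE),
                     class = "GenotypeCall"))
  }
  if (sum(depth$counts) == 0) {
    return(structure(list(group = group, copy = copy, combos = list(),
                          score = NA_real_, resolution = NA_integer_,
                          status = "no_reads", locked = FALSE),
                     class = "GenotypeCall"))
  }
  snps <- call_snps(depth, params)
  bases <- comparison_bases(db, frame, snps$pos, params$comparison_set)
  keep <- scoring_scope(snps, frame, bases, params)
  snps <- snps[keep, , drop = FALSE]
  bases <- bases[, keep, drop = FALSE]
  sc <- score_combinations(snps, bases, copy, params)
  combos7 <- sc$combos
  if (length(combos7) == 1L) {
    resolution <- 7L
    combos <- combos7
  } else {
    c5 <- unique(lapply(combos7, function(x) sort(allele_resolution(x, 5L))))
    if (length(c5) == 1L) {
      resolution <- 5L
      combos <- combos7 # keep full names; collapse at formatting
    } else {
      resolution <- NA_integer_
      combos <- combos7
    }
  }
  status <- if (!is.na(resolution)) "resolved" else "ambiguous"
  if (params$stage == "final" && sc$score > 0) status <- "unresolved"
  locked <- resolution %in% 7L && sc$score == 0
  structure(list(group = group, copy = copy, combos = combos,
                 score = sc$score, resolution = resolution,
                 status = status, locked = locked),
            class = "GenotypeCall")
}

#' @export
print.GenotypeCall <- function(x, ...) {
  g <- if (length(x$combos)) {
    paste(vapply(x$combos, paste, "", collapse = "+"), collapse = " | ")
  } else "-"
  cat(sprintf("GenotypeCall %s copy=%d %s score=%s %s\n", x$group,
              x$copy, x$status, format(x$score), g))
  invisible(x)
}

#' Format final genotype calls into a per-sample table
#'
#' Adds null alleles for genes with copy 0 or 1, merges the configured
#' allelic-group pairs into single output columns, renders component
#' alleles at 5-digit resolution, and renders ambiguity as a sorted,
#' `|`-separated list of alternatives.
#'
#' @param calls named list of `GenotypeCall`s (one per group).
#' @param copies named integer copy vector per group.
#' @param merges named list: output label -> the pair of merged groups.
#' @return data.frame with columns `gene`, `copy`, `genotype`, `status`,
#'   `score`.
#' @export
format_genotypes <- function(calls, copies, merges = list()) {
  groups <- names(copies)
  merged_members <- unlist(merges, use.names = FALSE)
  components <- function(g) {
    call <- calls[[g]]
    cp <- copies[[g]]
    alts <- if (is.null(call) || !length(call$combos)) list(character())
            else lapply(call$combos, function(x) {
              sort(allele_resolution(x, 5L))
            })
    unique(alts)
  }
  status_of <- function(gs) {
    st <- vapply(gs, function(g) {
      if (is.null(calls[[g]])) "null" else calls[[g]]$status
    }, "")
    prio <- c("no_reads", "unresolved", "ambiguous", "resolved", "null")
    prio[min(match(st, prio))]
  }
  score_of <- function(gs) {
    s <- vapply(gs, function(g) {
      if (is.null(calls[[g]])) 0 else as.numeric(calls[[g]]$score)
    }, 0)
    sum(s)
  }
  rows <- list()
  emit <- function(label, gs) {
    alt_sets <- lapply(gs, components)
    cross <- Reduce(function(a, b) {
      unlist(lapply(a, function(x) lapply(b, function(y) c(x, y))),
             recursive = FALSE)
    }, alt_sets)
    total <- sum(copies[gs])
    # null alleles fill the open slots of a locus at copy 0 or 1
    cross <- lapply(cross, function(x) {
      c(x, rep("null", max(0L, 2L - total)))
    })
    strs <- sort(unique(vapply(cross, function(x) {
      paste(sort(x), collapse = "+")
    }, "")))
    rows[[label]] <<- data.frame(
      gene = label, copy = sum(copies[gs]),
      genotype = paste(strs, collapse = "|"),
      status = status_of(gs), score = score_of(gs),
      stringsAsFactors = FALSE)
  }
  for (lab in names(merges)) emit(lab, merges[[lab]])
  for (g in setdiff(groups, merged_members)) emit(g, g)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), ]
}
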