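# Independent brute-force oracles used to check the optimized
# implementations on small instances.  These deliberately re-derive each
# quantity by direct definition (loops, full scans), not by calling the
# code paths they verify.

# all placements of `read` on `refs` within `max_mm` mismatches, both
# strands, by full sliding-window scan ('N' in the reference matches any
# base at no penalty)
naive_align <- function(read, refs, max_mm) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else revcomp(read)
    sv <- strsplit(s, "")[[1]]
    n <- length(sv)
    for (rn in names(refs)) {
      rv <- strsplit(refs[[rn]], "")[[1]]
      if (length(rv) < n) next
      for (start in seq_len(length(rv) - n + 1L)) {
        win <- rv[start:(start + n - 1L)]
        mm <- sum(win != sv & win != "N")
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <-
            data.frame(ref = rn, pos = start - 1L, strand = strand,
                       nmis = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), pos = integer(),
                      strand = character(), nmis = integer()))
  }
  do.call(rbind, out)
}

# distinct k-mers by explicit window loop
naive_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (!grepl("N", w, fixed = TRUE)) out <- c(out, w)
    }
  }
  unique(out)
}

# count of distinct read sequences containing the probe, explicit loop
naive_probe_count <- function(reads, probe) {
  u <- unique(unname(reads))
  rc <- revcomp(probe)
  n <- 0L
  for (r in u) {
    hit <- FALSE
    for (p in c(probe, rc)) {
      if (nchar(p) <= nchar(r)) {
        for (i in seq_len(nchar(r) - nchar(p) + 1L)) {
          if (substr(r, i, i + nchar(p) - 1L) == p) { hit <- TRUE; break }
        }
      }
      if (hit) break
    }
    if (hit) n <- n + 1L
  }
  n
}

# per-column imputation by direct scan: the unique characterized state
# or NA when the column is variable or uncovered
naive_impute_column <- function(column_chars) {
  known <- column_chars[column_chars != "N"]
  if (length(unique(known)) == 1L) unique(known) else NA_character_
}

# brute-force genotype combination scoring by direct definition:
# enumerate every assignment of `copy` alleles, score each position from
# scratch
naive_score_combinations <- function(snps, bases, copy, params) {
  alleles <- rownames(bases)
  hom <- which(snps$zygosity == 1L)
  het <- which(snps$zygosity >= 2L)
  hom_called <- sub(",.*", "", snps$variants[hom])
  hscore <- sapply(alleles, function(a) {
    s <- 0L
    for (j in seq_along(hom)) {
      b <- bases[a, hom[j]]
      if (b == "N") {
        if (params$uncharacterized_policy == "mismatch") s <- s + 1L
      } else if (b != hom_called[j]) s <- s + 1L
    }
    s
  })
  retained <- alleles[hscore <= min(hscore) + params$hom_buffer]
  grids <- rep(list(seq_along(retained)), copy)
  combos <- unique(lapply(
    split(as.matrix(do.call(expand.grid, grids)),
          seq_len(length(retained)^copy)),
    sort))
  best_score <- Inf
  best <- list()
  for (cmb in combos) {
    members <- retained[cmb]
    s <- sum(hscore[members])
    for (j in het) {
      called <- strsplit(snps$variants[j], ",")[[1]]
      off <- bases[members, j]
      nN <- sum(off == "N")
      real <- setdiff(unique(off), "N")
      miss <- length(setdiff(called, real))
      extra <- length(setdiff(real, called))
      s <- s + if (params$uncharacterized_policy == "match") {
        max(0L, miss - nN) + extra
      } else {
        miss + extra + as.integer(nN > 0L)
      }
    }
    if (s < best_score) { best_score <- s; best <- list(sort(members)) }
    else if (s == best_score) best <- c(best, list(sort(members)))
  }
  list(combos = unique(best), score = best_score)
}

# greedy-free exact max-min diversity: the best min-pairwise-distance
# achievable by any subset of the given size (distances over shared
# characterized positions)
exact_best_minimum_distance <- function(seqs, size) {
  nm <- names(seqs)
  d <- function(a, b) {
    va <- strsplit(seqs[[a]], "")[[1]]
    vb <- strsplit(seqs[[b]], "")[[1]]
    sum(va != vb & va != "N" & vb != "N")
  }
  subsets <- combn(nm, size, simplify = FALSE)
  best <- -Inf
  for (ss in subsets) {
    dmin <- min(apply(combn(ss, 2L), 2L, function(p) d(p[1], p[2])))
    if (dmin > best) best <- dmin
  }
  best
}
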