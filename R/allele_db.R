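# Allele database ingestion and preprocessing: MSA-based imputation of
# uncharacterized positions, UTR extension with donor sequence, and
# selection of a minimized, diversity-maximizing reference allele set.
#
# Conventions
#   * sequences: uppercase strings over A,C,G,T,N; 'N' iff uncharacterized
#   * masks: per-position strings over {0,1,2}: 0 uncharacterized,
#     1 natively characterized, 2 characterized by imputation / extension
#   * coordinates: 0-based half-open internally, 1-based closed in files
#   * an allele's "group" (major allelic group) defaults to its gene and
#     is the unit used for unique-read classification and genotyping

#' Construct an allele database
#'
#' @param alleles data.frame with columns `allele`, `gene`, `group`,
#'   `seq` (string over ACGTN) and optionally `mask` (string over 012 of
#'   equal length; derived from 'N' positions when absent).
#' @param features data.frame with columns `allele`, `feature`
#'   (`5UTR`, `exon_k`, `intron_k`, `3UTR`), `start`, `end`
#'   (0-based half-open).
#' @param msas named list, one gapped alignment per gene: a named
#'   character vector of rows over `ACGTN-`, names being allele names.
#' @param donors data.frame with columns `gene`, `group`, `side`
#'   (`"5"` or `"3"`) and `seq`: UTR donor sequences used by
#'   [extend_utrs()]. May be empty.
#' @param framework name of the framework gene assumed present at two
#'   copies in every sample (the depth normalizer).
#' @return an `AlleleDatabase` object.
#' @export
allele_database <- function(alleles, features, msas, donors, framework) {
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (is.null(alleles$mask)) {
    alleles$mask <- vapply(alleles$seq, function(s) {
      chartr("ACGTN", "11110", s)
    }, character(1), USE.NAMES = FALSE)
  }
  if (is.null(alleles$pad5)) alleles$pad5 <- 0L
  if (is.null(alleles$pad3)) alleles$pad3 <- 0L
  db <- structure(list(
    alleles = alleles,
    features = as.data.frame(features, stringsAsFactors = FALSE),
    msas = msas,
    donors = as.data.frame(donors, stringsAsFactors = FALSE),
    framework = framework,
    utr_target = NA_integer_
  ), class = "AlleleDatabase")
  validate_database(db)
  db
}

#' @export
print.AlleleDatabase <- function(x, ...) {
  cat(sprintf(
    "AlleleDatabase: %d alleles, %d genes, %d groups (framework %s)\n",
    nrow(x$alleles), length(unique(x$alleles$gene)),
    length(unique(x$alleles$group)), x$framework))
  invisible(x)
}

#' Validate allele database invariants
#'
#' Checks that masks match sequence 'N' placement, features tile each
#' allele without gaps or overlaps, and ungapping each MSA row reproduces
#' the stored allele sequence.
#'
#' @param db an `AlleleDatabase`.
#' @return `db` invisibly; stops with an informative error on violation.
#' @export
validate_database <- function(db) {
  al <- db$alleles
  stopifnot(!anyDuplicated(al$allele))
  bad <- which(nchar(al$seq) != nchar(al$mask))
  if (length(bad)) {
    stop("mask length mismatch for allele(s): ",
         paste(al$allele[bad], collapse = ", "))
  }
  for (i in seq_len(nrow(al))) {
    n_in_seq <- gregexpr("N", al$seq[i], fixed = TRUE)[[1]]
    n_in_mask <- gregexpr("0", al$mask[i], fixed = TRUE)[[1]]
    if (!identical(n_in_seq, n_in_mask)) {
      stop("allele ", al$allele[i],
           ": 'N' positions do not match uncharacterized mask positions")
    }
  }
  # feature tiling
  for (a in al$allele) {
    fe <- db$features[db$features$allele == a, , drop = FALSE]
    if (!nrow(fe)) stop("allele ", a, " has no feature annotation")
    fe <- fe[order(fe$start), ]
    len <- nchar(al$seq[al$allele == a])
    if (fe$start[1] != 0L || fe$end[nrow(fe)] != len ||
        (nrow(fe) > 1 && any(fe$start[-1] != fe$end[-nrow(fe)]))) {
      stop("features of allele ", a,
           " do not tile [0, ", len, ") without gaps or overlaps")
    }
  }
  # MSA consistency (native portion of each sequence)
  for (g in names(db$msas)) {
    rows <- db$msas[[g]]
    if (!length(rows)) stop("empty MSA for gene ", g)
    if (length(unique(nchar(rows))) != 1L) {
      stop("MSA rows of gene ", g, " differ in column count")
    }
    unknown <- setdiff(names(rows), al$allele)
    if (length(unknown)) {
      stop("MSA of gene ", g, " names unknown allele(s): ",
           paste(unknown, collapse = ", "))
    }
    for (a in names(rows)) {
      ungapped <- gsub("-", "", rows[[a]], fixed = TRUE)
      i <- match(a, al$allele)
      native <- substr(al$seq[i], al$pad5[i] + 1L,
                       nchar(al$seq[i]) - al$pad3[i])
      if (!identical(ungapped, native)) {
        stop("ungapped MSA row for allele ", a,
             " differs from its stored sequence")
      }
    }
  }
  if (!db$framework %in% al$gene) {
    stop("framework gene ", db$framework, " absent from database")
  }
  invisible(db)
}

#' Parse an allele database from files
#'
#' FASTA headers must follow the grammar `GENE*NNNNNNN[ group=GROUP]`:
#' the gene label, a literal `*`, the allele digits (3/5/7-digit
#' resolution semantics), and an optional major-allelic-group override.
#' Feature tables are TSV with 1-based closed `start`/`end` columns.
#'
#' @param allele_fasta path to the allele FASTA.
#' @param msa_files named character vector of per-gene aligned FASTA
#'   paths (names are gene labels).
#' @param feature_table path to the feature TSV
#'   (`allele`, `feature`, `start`, `end`).
#' @param donor_fasta optional FASTA of UTR donors with headers
#'   `GENE:GROUP:5` / `GENE:GROUP:3`.
#' @param framework framework gene label.
#' @return an `AlleleDatabase`.
#' @export
parse_database <- function(allele_fasta, msa_files, feature_table,
                           donor_fasta = NULL, framework) {
  seqs <- read_fasta(allele_fasta)
  hdr <- "^([A-Za-z0-9_.-]+)\\*([0-9]+)( group=([A-Za-z0-9_.-]+))?$"
  bad <- grep(hdr, names(seqs), invert = TRUE)
  if (length(bad)) {
    stop("FASTA record(s) ", paste(bad, collapse = ", "),
         " of ", allele_fasta, " do not match the header grammar ",
         "'GENE*DIGITS[ group=GROUP]'")
  }
  gene <- sub(hdr, "\\1", names(seqs))
  grp <- sub(hdr, "\\4", names(seqs))
  grp[grp == ""] <- gene[grp == ""]
  allele <- paste0(gene, "*", sub(hdr, "\\2", names(seqs)))
  alleles <- data.frame(allele = allele, gene = gene, group = grp,
                        seq = unname(seqs), stringsAsFactors = FALSE)

  fe <- read.delim(feature_table, stringsAsFactors = FALSE)
  need <- c("allele", "feature", "start", "end")
  if (!all(need %in% names(fe))) {
    stop("feature table ", feature_table, " lacks column(s): ",
         paste(setdiff(need, names(fe)), collapse = ", "))
  }
  fe$start <- fe$start - 1L # to 0-based half-open

  msas <- lapply(seq_along(msa_files), function(i) {
    rows <- read_fasta(msa_files[[i]])
    if (!length(rows)) stop("empty MSA file: ", msa_files[[i]])
    rows
  })
  names(msas) <- names(msa_files)

  donors <- data.frame(gene = character(), group = character(),
                       side = character(), seq = character())
  if (!is.null(donor_fasta)) {
    ds <- read_fasta(donor_fasta)
    parts <- strsplit(names(ds), ":", fixed = TRUE)
    ok <- lengths(parts) == 3L
    if (!all(ok)) stop("donor header(s) not matching 'GENE:GROUP:SIDE'")
    donors <- data.frame(
      gene = vapply(parts, `[`, "", 1L),
      group = vapply(parts, `[`, "", 2L),
      side = vapply(parts, `[`, "", 3L),
      seq = unname(ds), stringsAsFactors = FALSE)
  }
  allele_database(alleles, fe, msas, donors, framework)
}

#' Impute uncharacterized MSA positions from characterized rows
#'
#' For each row and each uncharacterized column, the column receives the
#' consensus character when every row characterized at that column agrees
#' (invariant column); columns that are variable among characterized rows,
#' or characterized in no row, stay `N`.  Characterized positions are
#' never altered.  A gap (`-`) counts as a characterized state, so an
#' invariant deletion can be imputed.
#'
#' @param rows named character vector: gapped MSA rows over `ACGTN-`.
#' @return list with `rows` (imputed), `filled` (per-row integer vectors
#'   of imputed column indices) and `uncovered` (columns characterized in
#'   no row).
#' @export
impute_msa <- function(rows) {
  mat <- do.call(rbind, seq_chars(rows))
  known <- mat != "N"
  ncols <- ncol(mat)
  consensus <- rep(NA_character_, ncols)
  for (j in seq_len(ncols)) {
    vals <- unique(mat[known[, j], j])
    if (length(vals) == 1L) consensus[j] <- vals
  }
  uncovered <- which(colSums(known) == 0L)
  filled <- vector("list", nrow(mat))
  names(filled) <- names(rows)
  for (i in seq_len(nrow(mat))) {
    fill <- which(!known[i, ] & !is.na(consensus))
    mat[i, fill] <- consensus[fill]
    filled[[i]] <- fill
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- names(rows)
  list(rows = out, filled = filled, uncovered = uncovered)
}

#' Impute every gene MSA of a database
#'
#' Applies [impute_msa()] per gene and writes the imputed bases back into
#' the allele sequences, flagging them in the mask as
#' characterized-by-imputation (`2`) so that scoring stages can
#' distinguish native from imputed sequence.
#'
#' @param db an `AlleleDatabase` (unextended).
#' @return the imputed database.
#' @export
impute_database <- function(db) {
  for (g in names(db$msas)) {
    imp <- impute_msa(db$msas[[g]])
    for (a in names(imp$rows)) {
      i <- match(a, db$alleles$allele)
      gapped <- imp$rows[[a]]
      new_native <- gsub("-", "", gapped, fixed = TRUE)
      old <- db$alleles$seq[i]
      pad5 <- db$alleles$pad5[i]
      core_len <- nchar(old) - pad5 - db$alleles$pad3[i]
      stopifnot(nchar(new_native) == core_len)
      mask <- db$alleles$mask[i]
      # positions (within native core) that changed from N were imputed
      changed <- which(seq_chars(substr(old, pad5 + 1L,
                                        pad5 + core_len))[[1]] == "N" &
                       seq_chars(new_native)[[1]] != "N")
      stringi::stri_sub(old, pad5 + 1L, pad5 + core_len) <- new_native
      mask <- sub_positions(mask, pad5 + changed, "2")
      db$alleles$seq[i] <- old
      db$alleles$mask[i] <- mask
    }
    db$msas[[g]] <- imp$rows
  }
  db
}

#' Extend untranslated regions to a target length with donor sequence
#'
#' Appends the outer portion of each gene/group donor so that every
#' allele's 5' and 3' UTR features span exactly `target_len` bases;
#' internal feature coordinates are shifted accordingly.  Appended bases
#' are flagged in the mask as characterized-by-extension (`2`).
#'
#' @param db an `AlleleDatabase` with donors for every gene x group in
#'   need of extension.
#' @param target_len target UTR length in bp (default 1000).
#' @return the extended database.
#' @export
extend_utrs <- function(db, target_len = 1000L) {
  target_len <- as.integer(target_len)
  for (i in seq_len(nrow(db$alleles))) {
    a <- db$alleles$allele[i]
    g <- db$alleles$gene[i]
    grp <- db$alleles$group[i]
    fe <- db$features[db$features$allele == a, , drop = FALSE]
    fe <- fe[order(fe$start), ]
    u5 <- fe[fe$feature == "5UTR", ]
    u3 <- fe[fe$feature == "3UTR", ]
    stopifnot(nrow(u5) == 1L, nrow(u3) == 1L)
    d5 <- target_len - (u5$end - u5$start)
    d3 <- target_len - (u3$end - u3$start)
    if (d5 < 0L || d3 < 0L) {
      stop("allele ", a, " has UTRs longer than target_len")
    }
    pre <- post <- ""
    if (d5 > 0L) {
      don <- db$donors$seq[db$donors$gene == g & db$donors$group == grp &
                           db$donors$side == "5"]
      if (!length(don)) stop("missing 5' UTR donor for ", g, "/", grp)
      if (nchar(don) < target_len) {
        stop("5' donor for ", g, "/", grp,
             " shorter than target UTR length")
      }
      pre <- substr(don, 1L, d5) # outermost portion of the donor
    }
    if (d3 > 0L) {
      don <- db$donors$seq[db$donors$gene == g & db$donors$group == grp &
                           db$donors$side == "3"]
      if (!length(don)) stop("missing 3' UTR donor for ", g, "/", grp)
      if (nchar(don) < target_len) {
        stop("3' donor for ", g, "/", grp,
             " shorter than target UTR length")
      }
      post <- substr(don, nchar(don) - d3 + 1L, nchar(don))
    }
    db$alleles$seq[i] <- paste0(pre, db$alleles$seq[i], post)
    db$alleles$mask[i] <- paste0(strrep("2", d5), db$alleles$mask[i],
                                 strrep("2", d3))
    db$alleles$pad5[i] <- db$alleles$pad5[i] + d5
    db$alleles$pad3[i] <- db$alleles$pad3[i] + d3
    sel <- db$features$allele == a
    db$features$start[sel] <- db$features$start[sel] + d5
    db$features$end[sel] <- db$features$end[sel] + d5
    sel5 <- sel & db$features$feature == "5UTR"
    db$features$start[sel5] <- 0L
    sel3 <- sel & db$features$feature == "3UTR"
    db$features$end[sel3] <- db$features$end[sel3] + d3
  }
  db$utr_target <- target_len
  db
}

#' Per-allele sequence completeness
#'
#' Characterized length of each allele divided by the longest allele
#' length of its gene/major group, natively (`frac_native`) and counting
#' imputed or extended positions as characterized (`frac_imputed`).
#'
#' @param db an `AlleleDatabase`.
#' @return data.frame with one row per allele.
#' @export
completeness_report <- function(db) {
  al <- db$alleles
  len <- nchar(al$seq)
  longest <- stats::ave(len, al$group, FUN = max)
  n_native <- stringi::stri_count_fixed(al$mask, "1")
  n_imp <- n_native + stringi::stri_count_fixed(al$mask, "2")
  data.frame(allele = al$allele, gene = al$gene, group = al$group,
             length = len,
             frac_native = n_native / longest,
             frac_imputed = n_imp / longest,
             stringsAsFactors = FALSE)
}

#' Select a minimized, diversity-maximizing reference allele set
#'
#' Picks up to `per_group` alleles per gene/major group: forced
#' sequestration alleles first, then the most complete allele, then
#' greedy max-min pairwise Hamming distance (computed over mutually
#' characterized MSA columns) among the nearly-complete candidates.
#' Ties break on lexicographic allele name, so the selection is
#' deterministic given the database.
#'
#' @param db imputed (and typically extended) `AlleleDatabase`.
#' @param per_group maximum alleles per group (default 5).
#' @param force_include allele names that must be part of the set
#'   (e.g. sequestration alleles that attract off-gene reads).
#' @return a `ReferenceSet`.
#' @export
select_minimized_reference <- function(db, per_group = 5L,
                                       force_include = character()) {
  comp <- completeness_report(db)
  chosen <- character()
  for (grp in sort(unique(db$alleles$group))) {
    cand <- comp[comp$group == grp, ]
    cand <- cand[order(-cand$frac_imputed, cand$allele), ]
    if (nrow(cand) <= per_group) {
      if (nrow(cand) < per_group) {
        warning("group ", grp, " has fewer than ", per_group,
                " alleles; including all")
      }
      chosen <- c(chosen, cand$allele)
      next
    }
    # nearly-complete candidate pool, widened until large enough
    pool <- cand$allele[cand$frac_imputed >= 0.95 * max(cand$frac_imputed)]
    if (length(pool) < per_group) pool <- cand$allele[seq_len(per_group)]
    pick <- intersect(force_include, cand$allele)
    if (!length(pick)) pick <- pool[1L]
    pool <- union(pool, pick)
    rest <- setdiff(pool, pick)
    gene <- db$alleles$gene[match(pool[1L], db$alleles$allele)]
    rows <- db$msas[[gene]]
    seqs <- if (!is.null(rows) && all(pool %in% names(rows))) {
      rows[pool] # distances over shared MSA columns
    } else {
      setNames(db$alleles$seq[match(pool, db$alleles$allele)], pool)
    }
    while (length(pick) < per_group && length(rest)) {
      dmin <- vapply(rest, function(a) {
        min(cpp_pair_mismatch(rep(seqs[[a]], length(pick)),
                              unname(seqs[pick])))
      }, numeric(1))
      best <- rest[dmin == max(dmin)]
      pick <- c(pick, sort(best)[1L])
      rest <- setdiff(rest, pick)
    }
    chosen <- c(chosen, pick)
  }
  chosen <- union(intersect(force_include, db$alleles$allele), chosen)
  reference_set("minimized", sort(chosen))
}

#' Construct a reference set
#'
#' A named collection of allele names used as an alignment reference.
#'
#' @param label descriptive label.
#' @param alleles character vector of allele names.
#' @return a `ReferenceSet`.
#' @export
reference_set <- function(label, alleles) {
  structure(list(label = label, alleles = unique(alleles)),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet '%s': %d alleles\n", x$label,
              length(x$alleles)))
  invisible(x)
}

#' Pull reference sequences for a reference set
#'
#' @param db an `AlleleDatabase`.
#' @param refset a `ReferenceSet`, or a character vector of allele names.
#' @param unimputed if `TRUE`, return sequences with imputed/extended
#'   positions reverted to `N`.
#' @return named character vector of sequences.
#' @export
reference_sequences <- function(db, refset, unimputed = FALSE) {
  alleles <- if (inherits(refset, "ReferenceSet")) refset$alleles
             else refset
  i <- match(alleles, db$alleles$allele)
  if (anyNA(i)) {
    stop("unknown allele(s): ", paste(alleles[is.na(i)], collapse = ", "))
  }
  seqs <- db$alleles$seq[i]
  if (unimputed) {
    seqs <- mapply(function(s, m) {
      sub_positions(s, which(seq_chars(m)[[1]] == "2"), "N")
    }, seqs, db$alleles$mask[i], USE.NAMES = FALSE)
  }
  setNames(seqs, alleles)
}

#' Map allele names to groups
#' @noRd
allele_groups <- function(db, alleles) {
  db$alleles$group[match(alleles, db$alleles$allele)]
}

#' Write database artifacts to a directory
#'
#' Emits the (possibly imputed/extended) allele FASTA, per-gene MSA
#' FASTA, feature TSV (1-based closed coordinates), donor FASTA, and a
#' completeness TSV.
#'
#' @param db an `AlleleDatabase`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  al <- db$alleles
  hdr <- ifelse(al$group == al$gene, al$allele,
                paste0(al$allele, " group=", al$group))
  write_fasta(setNames(al$seq, hdr), file.path(dir, "alleles.fasta"))
  for (g in names(db$msas)) {
    write_fasta(db$msas[[g]], file.path(dir, paste0("msa_", g, ".fasta")))
  }
  fe <- db$features
  fe$start <- fe$start + 1L
  write.table(fe, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(db$donors)) {
    write_fasta(setNames(db$donors$seq,
                         paste(db$donors$gene, db$donors$group,
                               db$donors$side, sep = ":")),
                file.path(dir, "donors.fasta"))
  }
  write.table(completeness_report(db), file.path(dir, "completeness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
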