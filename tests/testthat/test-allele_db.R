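# Allele database ingestion, imputation, UTR extension, completeness
# and minimized reference selection.

test_that("database round-trips through files and validates invariants", {
  db <- make_toy_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  msa_files <- setNames(file.path(dir, c("msa_GA.fasta", "msa_GB.fasta")),
                        c("GA", "GB"))
  db2 <- parse_database(file.path(dir, "alleles.fasta"), msa_files,
                        file.path(dir, "features.tsv"),
                        donor_fasta = file.path(dir, "donors.fasta"),
                        framework = "GA")
  expect_equal(sort(db2$alleles$allele), sort(db$alleles$allele))
  i <- match(db$alleles$allele, db2$alleles$allele)
  expect_identical(db2$alleles$seq[i], db$alleles$seq)
  expect_identical(db2$alleles$mask[i], db$alleles$mask)
  expect_equal(length(db2$msas), 2L)
})

test_that("malformed inputs are rejected with informative errors", {
  db <- make_toy_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  # header not matching the grammar
  bad <- file.path(dir, "bad.fasta")
  writeLines(c(">not a valid header", "ACGT"), bad)
  msa_files <- setNames(file.path(dir, c("msa_GA.fasta", "msa_GB.fasta")),
                        c("GA", "GB"))
  expect_error(parse_database(bad, msa_files,
                              file.path(dir, "features.tsv"),
                              framework = "GA"),
               "header grammar")
  # FASTA sequence inconsistent with its MSA row
  al <- db$alleles
  al$seq[1] <- paste0("T", substr(al$seq[1], 2, nchar(al$seq[1])))
  al$mask <- NULL
  expect_error(allele_database(al, db$features, db$msas, db$donors, "GA"),
               "differs from its stored sequence")
  # empty MSA file
  empty <- file.path(dir, "empty.fasta")
  file.create(empty)
  expect_error(parse_database(file.path(dir, "alleles.fasta"),
                              setNames(c(msa_files[1], empty),
                                       c("GA", "GB")),
                              file.path(dir, "features.tsv"),
                              framework = "GA"),
               "empty.fasta")
})

test_that("imputation fills invariant columns only and is idempotent", {
  # forced-by-definition example: invariant columns imputed
  imp <- impute_msa(c(A = "ACGT", B = "NCGN"))
  expect_identical(unname(imp$rows[["B"]]), "ACGT")
  # variable column stays N
  imp <- impute_msa(c(A = "ACGT", C = "AGGT", B = "NNGT"))
  expect_identical(unname(imp$rows[["B"]]), "ANGT")
  # fully characterized rows unchanged
  expect_identical(unname(imp$rows[["A"]]), "ACGT")
  # column with zero characterized rows stays N and is reported
  imp <- impute_msa(c(A = "ANG", B = "ANG"))
  expect_identical(imp$uncovered, 2L)
  expect_identical(unname(imp$rows[["A"]]), "ANG")
  # idempotence and per-column oracle on random masked alignments
  set.seed(71)
  for (rep in 1:5) {
    n <- 6L; len <- 40L
    base <- sample(c("A", "C", "G", "T"), len, TRUE)
    mat <- matrix(rep(base, n), n, len, byrow = TRUE)
    mat[sample(length(mat), 25L)] <-
      sample(c("A", "C", "G", "T"), 25L, TRUE)
    masked <- mat
    masked[sample(length(mat), 60L)] <- "N"
    rows <- setNames(apply(masked, 1L, paste, collapse = ""),
                     paste0("al", seq_len(n)))
    imp <- impute_msa(rows)
    # characterized positions never change
    for (i in seq_len(n)) {
      known <- masked[i, ] != "N"
      expect_identical(strsplit(imp$rows[[i]], "")[[1]][known],
                       masked[i, known])
    }
    # independent per-column oracle
    for (j in seq_len(len)) {
      expected <- naive_impute_column(masked[, j])
      for (i in which(masked[, j] == "N")) {
        got <- substr(imp$rows[[i]], j, j)
        expect_identical(got,
                         if (is.na(expected)) "N" else expected)
      }
    }
    expect_identical(impute_msa(imp$rows)$rows, imp$rows)
  }
})

test_that("UTR extension pads to the target and shifts coordinates", {
  db <- make_toy_db()
  ext <- extend_utrs(db, target_len = 30L)
  a <- ext$alleles$allele[1]
  fe <- ext$features[ext$features$allele == a, ]
  expect_equal(fe$end[fe$feature == "5UTR"] - fe$start[fe$feature == "5UTR"],
               30L)
  expect_equal(fe$end[fe$feature == "3UTR"] - fe$start[fe$feature == "3UTR"],
               30L)
  # exon coordinates shifted by the 5' deficit (30 - 10 = 20)
  expect_equal(fe$start[fe$feature == "exon_1"], 10L + 20L)
  # appended sequence is the donor's outer portion
  don5 <- db$donors$seq[db$donors$gene == "GA" & db$donors$side == "5"]
  expect_identical(substr(ext$alleles$seq[1], 1, 20), substr(don5, 1, 20))
  # exon bytes preserved
  expect_identical(substr(ext$alleles$seq[1], 31, 50),
                   substr(db$alleles$seq[1], 11, 30))
  # already-at-target alleles unchanged
  ext2 <- extend_utrs(ext, target_len = 30L)
  expect_identical(ext2$alleles$seq, ext$alleles$seq)
  # donor shorter than the deficit errors
  expect_error(extend_utrs(db, target_len = 100L), "shorter than target")
  validate_database(ext)
})

test_that("completeness fractions are correct and imputation monotone", {
  db <- make_toy_db()
  rep0 <- completeness_report(db)
  # fully characterized alleles sit at 1
  expect_equal(rep0$frac_native[rep0$allele == "GA*0010101"], 1)
  # the exons-only allele is characterized over 30 of 60 positions
  expect_equal(rep0$frac_native[rep0$allele == "GA*0010201"], 0.5)
  rep1 <- completeness_report(impute_database(db))
  expect_true(all(rep1$frac_imputed >= rep0$frac_native))
})

test_that("minimized reference selection is diverse and deterministic", {
  fam <- packaged_family()
  db <- fam$prepared
  # brute-force max-min oracle on one group
  grp <- "DS1"
  pool <- db$alleles$allele[db$alleles$group == grp]
  seqs <- setNames(db$alleles$seq[match(pool, db$alleles$allele)], pool)
  sel <- suppressWarnings(select_minimized_reference(db, per_group = 5L))
  picked <- grep("^DS1", sel$alleles, value = TRUE)
  expect_length(picked, 5L)
  expect_true(all(picked %in% pool))
  # determinism
  sel2 <- suppressWarnings(select_minimized_reference(db, per_group = 5L))
  expect_identical(sel$alleles, sel2$alleles)
  # near-identical alleles are not both taken before more distant ones:
  # the greedy selection achieves at least half the exact max-min
  # dispersion bound (classic greedy guarantee), checked by brute force
  # over all 5-subsets of the 8 DS1 alleles
  dmin_sel <- min(apply(combn(picked, 2L), 2L, function(p) {
    sum(strsplit(seqs[[p[1]]], "")[[1]] !=
        strsplit(seqs[[p[2]]], "")[[1]])
  }))
  exact <- exact_best_minimum_distance(seqs, length(picked))
  expect_gte(dmin_sel, exact / 2)
  # forced sequestration alleles are present
  forced <- pool[3]
  sel3 <- suppressWarnings(
    select_minimized_reference(db, per_group = 5L,
                               force_include = forced))
  expect_true(forced %in% sel3$alleles)
  # a group smaller than per_group is included wholesale, with warning
  toy <- make_toy_db()
  w <- capture_warnings(s <- select_minimized_reference(toy, per_group = 5L))
  expect_true(all(grepl("fewer than", w)))
  expect_length(w, 2L) # one per undersized group
  expect_setequal(s$alleles, toy$alleles$allele)
})
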