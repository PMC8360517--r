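# Built-in aligner, unique-read classification and depth tables.

test_that("aligner equals the sliding-window oracle on small instances", {
  set.seed(21)
  refs <- setNames(
    replicate(3, paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = "")),
    c("r1", "r2", "r3"))
  # make r2 a near-copy of r1 so multi-placement reads exist
  v <- strsplit(refs[["r1"]], "")[[1]]
  v[sample(400, 6)] <- sample(c("A", "C", "G", "T"), 6, TRUE)
  refs[["r2"]] <- paste(v, collapse = "")
  reads <- character()
  for (i in 1:12) {
    src <- sample(names(refs), 1)
    start <- sample(250, 1)
    r <- substr(refs[[src]], start, start + 79L)
    # sprinkle up to 2 mismatches
    nmut <- sample(0:2, 1)
    if (nmut) {
      vv <- strsplit(r, "")[[1]]
      vv[sample(80, nmut)] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
      r <- paste(vv, collapse = "")
    }
    if (sample(c(TRUE, FALSE), 1)) r <- revcomp(r)
    reads[paste0("q", i)] <- r
  }
  for (cap in c(1L, 3L)) {
    got <- as.data.frame(align_reads(reads, refs, mode = "exhaustive",
                                     max_mm = cap))
    for (q in names(reads)) {
      want <- naive_align(reads[[q]], refs, cap)
      sub <- got[got$read == q, c("ref", "pos", "strand", "nmis")]
      o1 <- do.call(order, want)
      o2 <- do.call(order, sub)
      rownames(want) <- rownames(sub) <- NULL
      expect_equal(sub[o2, ], want[o1, ], ignore_attr = TRUE)
    }
    # best mode is a subset at the per-read minimum
    best <- as.data.frame(align_reads(reads, refs, mode = "best",
                                      max_mm = cap))
    if (nrow(best)) {
      merged <- merge(best, got, by = names(best))
      expect_equal(nrow(merged), nrow(best))
      mins <- tapply(got$nmis, got$read, min)
      expect_true(all(best$nmis == mins[best$read]))
    }
  }
})

test_that("uncharacterized reference positions match any base freely", {
  set.seed(24)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  v <- strsplit(ref, "")[[1]]
  v[101:130] <- "N"
  refs <- c(rn = paste(v, collapse = ""))
  # read spanning the N patch, with arbitrary bases across it
  rd <- substr(ref, 61, 140)
  rd <- c(q = gsub("N", "G", paste(v[61:140], collapse = ""), fixed = TRUE))
  got <- align_reads(rd, refs, mode = "exhaustive", max_mm = 1L)
  expect_equal(got$pos, 60L)
  expect_equal(got$nmis, 0L)
  want <- naive_align(rd[["q"]], refs, 1L)
  expect_equal(nrow(want[want$strand == "+", ]), 1L)
  expect_equal(want$nmis[want$strand == "+"], 0L)
})

test_that("unique classification partitions aligned reads by group", {
  set.seed(22)
  ga <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  gb <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  shared <- substr(ga, 1, 80)
  gb <- paste0(shared, substr(gb, 81, 300)) # first 80 bp identical
  refs <- c(A1 = ga, A2 = ga, B1 = gb)
  grouping <- c(A1 = "GA", A2 = "GA", B1 = "GB")
  reads <- c(uniqA = substr(ga, 151, 210),
             uniqB = substr(gb, 151, 210),
             cross = substr(ga, 11, 70))
  rec <- align_reads(reads, refs, mode = "exhaustive", max_mm = 2L)
  uc <- classify_unique(rec, grouping)
  expect_equal(uc$read_group$group[uc$read_group$read == "uniqA"], "GA")
  expect_equal(uc$read_group$group[uc$read_group$read == "uniqB"], "GB")
  expect_identical(uc$cross, "cross")
  expect_equal(as.integer(uc$counts[c("GA", "GB")]), c(1L, 1L))
  # partition: unique sets and cross set cover all aligned reads
  expect_setequal(c(uc$read_group$read),
                  unique(rec$read))
  # grouping must cover every reference
  expect_error(classify_unique(rec, grouping[1:2]), "lacks reference")
})

test_that("depth tables count aligned bases at frame positions", {
  fam <- mini_family()
  db <- fam$prepared
  frame <- group_frame(db, "AA1")
  a <- frame$alleles[1]
  seqa <- db$alleles$seq[db$alleles$allele == a]
  # one error-free read increments its own bases
  rd <- setNames(substr(seqa, 301, 360), "x/1")
  rec <- align_reads(rd, reference_sequences(db, a), mode = "best",
                     max_mm = 2L)
  dt <- build_depth_table(rec, rd, frame)
  expect_equal(sum(dt$counts), 60)
  for (off in c(0L, 30L, 59L)) {
    b <- substr(seqa, 301 + off, 301 + off)
    expect_equal(unname(dt$counts[b, 301 + off]), 1L)
  }
  # a substituted base is counted at the mismatching variant
  rd2 <- rd
  b0 <- substr(rd2, 5, 5)
  alt <- setdiff(c("A", "C", "G", "T"), b0)[1]
  substr(rd2, 5, 5) <- alt
  rec2 <- align_reads(rd2, reference_sequences(db, a), mode = "best",
                      max_mm = 2L)
  dt2 <- build_depth_table(rec2, rd2, frame)
  expect_equal(unname(dt2$counts[alt, 305]), 1L)
  expect_equal(unname(dt2$counts[b0, 305]), 0L)
  # conservation bound: counted bases never exceed reads x read length
  expect_lte(sum(dt2$counts), nchar(rd2))
})

test_that("SAM round-trip preserves records", {
  set.seed(23)
  refs <- c(R1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                       collapse = ""))
  reads <- c("a/1" = substr(refs[["R1"]], 21, 80),
             "b/1" = revcomp(substr(refs[["R1"]], 101, 160)))
  rec <- align_reads(reads, refs, mode = "best", max_mm = 1L)
  expect_equal(nrow(rec), 2L)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(rec, reads, refs, path)
  back <- read_sam(path)
  expect_equal(back$records$pos, rec$pos)
  expect_equal(back$records$strand, rec$strand)
  expect_equal(back$records$nmis, rec$nmis)
  expect_identical(unname(back$reads[rec$read]), unname(reads[rec$read]))
})
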