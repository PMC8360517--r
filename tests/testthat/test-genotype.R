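# SNP calling and mismatch scoring.

# depth table fixture: given per-position variant depths over a tiny
# frame, build the 6 x L counts matrix
mk_depth <- function(spec, frame_len, exonic = rep(TRUE, frame_len)) {
  counts <- matrix(0L, 6L, frame_len,
                   dimnames = list(c("A", "C", "G", "T", "del", "ins"),
                                   NULL))
  for (s in spec) counts[s$base, s$pos] <- s$depth
  structure(list(counts = counts, offset = 0L, exonic = exonic),
            class = "DepthTable")
}

test_that("SNP calling applies depth floors and the variant ratio rule", {
  p_init <- scoring_params("initial")
  p_final <- scoring_params("final")
  depth <- mk_depth(list(list(base = "A", pos = 1, depth = 15L),
                         list(base = "G", pos = 1, depth = 5L),
                         list(base = "A", pos = 2, depth = 19L),
                         list(base = "A", pos = 3, depth = 16L),
                         list(base = "C", pos = 3, depth = 3L)),
                    frame_len = 4L)
  snp <- call_snps(depth, p_init)
  # 5/15 = 0.33 >= 0.25: heterozygous A,G
  expect_equal(snp$variants[snp$pos == 1], "A,G")
  expect_equal(snp$zygosity[snp$pos == 1], 2L)
  # 3/16 < 0.25: homozygous A
  expect_equal(snp$variants[snp$pos == 3], "A")
  # position 4 has no depth, dropped
  expect_false(4L %in% snp$pos)
  # final-stage floor of 20 drops a depth-19 position
  snp_f <- call_snps(depth, p_final)
  expect_false(2L %in% snp_f$pos)
  # initial-stage floor of 8 keeps it
  expect_true(2L %in% snp$pos)
  # at most three variants are recorded
  d3 <- mk_depth(list(list(base = "A", pos = 1, depth = 40L),
                      list(base = "C", pos = 1, depth = 30L),
                      list(base = "G", pos = 1, depth = 20L),
                      list(base = "T", pos = 1, depth = 15L)),
                 frame_len = 1L)
  expect_equal(call_snps(d3, p_init)$zygosity, 3L)
})

test_that("homozygous scoring honors the buffer and N policy", {
  p_init <- scoring_params("initial")
  p_final <- scoring_params("final")
  called <- c("A", "C", "G")
  expect_equal(score_homozygous(called, c("A", "C", "G"), p_init), 0L)
  expect_equal(score_homozygous(called, c("A", "T", "G"), p_init), 1L)
  # uncharacterized: full mismatch initially, match at the final stage
  expect_equal(score_homozygous(called, c("A", "N", "G"), p_init), 1L)
  expect_equal(score_homozygous(called, c("A", "N", "G"), p_final), 0L)
  # retention buffer: initial keeps scores within min + 4
  snps <- data.frame(pos = 1:6, variants = c("A", "A", "A", "A", "A", "A"),
                     depths = "30", zygosity = 1L, total = 30)
  bases <- rbind(best = rep("A", 6),
                 mid = c("C", "C", rep("A", 4)),
                 within = c(rep("C", 6)),
                 out = rep("C", 6))
  bases["within", ] <- c("C", "C", "C", "C", "A", "A")
  sc <- score_combinations(snps, bases, copy = 1L, p_init)
  expect_setequal(sc$retained, c("best", "mid", "within"))
  # final buffer of 1 is stricter
  sc_f <- score_combinations(snps, bases, copy = 1L, p_final)
  expect_setequal(sc_f$retained, c("best"))
})

test_that("combination scoring equals brute force on small instances", {
  set.seed(101)
  for (rep in 1:6) {
    n_all <- sample(4:8, 1)
    n_pos <- sample(4:9, 1)
    alleles <- paste0("G*00", seq_len(n_all), "0101")
    bases <- matrix(sample(c("A", "C", "G", "T", "N"), n_all * n_pos,
                           TRUE, prob = c(.23, .23, .23, .23, .08)),
                    n_all, n_pos, dimnames = list(alleles, NULL))
    zyg <- sample(1:2, n_pos, TRUE)
    variants <- vapply(seq_len(n_pos), function(j) {
      paste(sample(c("A", "C", "G", "T"), zyg[j]), collapse = ",")
    }, "")
    snps <- data.frame(pos = seq_len(n_pos), variants = variants,
                       depths = "30", zygosity = zyg, total = 30)
    copy <- sample(1:3, 1)
    params <- scoring_params(sample(c("initial", "final"), 1),
                             hom_buffer = sample(0:4, 1))
    got <- score_combinations(snps, bases, copy, params)
    want <- naive_score_combinations(snps, bases, copy, params)
    expect_equal(got$score, want$score)
    expect_setequal(lapply(got$combos, paste, collapse = "+"),
                    lapply(want$combos, paste, collapse = "+"))
  }
})

test_that("heterozygous positions score by symmetric difference", {
  p <- scoring_params("initial", hom_buffer = 10L)
  # call {A,G}; combination offering {A,A} scores +1
  snps <- data.frame(pos = 1L, variants = "A,G", depths = "20,10",
                     zygosity = 2L, total = 30)
  bases <- rbind("X*0010101" = "A", "Y*0010101" = "A", "Z*0010101" = "G")
  sc <- score_combinations(snps, bases, copy = 2L, p)
  expect_equal(sc$score, 0) # X+Z (or the equivalent Y+Z) offers {A,G}
  expect_setequal(vapply(sc$combos, paste, "", collapse = "+"),
                  c("X*0010101+Z*0010101", "Y*0010101+Z*0010101"))
  bases2 <- bases[1:2, , drop = FALSE]
  sc2 <- score_combinations(snps, bases2, copy = 2L, p)
  expect_equal(sc2$score, 1)
})

test_that("genotype resolution collapses 7-digit ties to 5-digit", {
  fam <- mini_family()
  db <- fam$prepared
  frame <- group_frame(db, "AA1")
  # homozygous truth for an allele with a 7-digit sibling: build depth
  # from error-free reads of that allele
  a <- grep("^AA1\\*0010101", db$alleles$allele, value = TRUE)
  seqa <- db$alleles$seq[db$alleles$allele == a]
  starts <- seq(1L, nchar(seqa) - 149L, by = 3L)
  reads <- setNames(substring(seqa, starts, starts + 149L),
                    paste0("r", seq_along(starts), "/1"))
  refs <- reference_sequences(db, frame$alleles)
  rec <- pick_primary(align_reads(reads, refs, mode = "best", max_mm = 6L))
  depth <- build_depth_table(rec, reads, frame)
  call_f <- genotype_group(db, "AA1", frame, depth, copy = 2L,
                           scoring_params("final"))
  # final stage sees exonic positions only, where the 7-digit sibling
  # is identical: ambiguity collapses to one 5-digit call
  expect_equal(call_f$status, "resolved")
  expect_equal(call_f$resolution, 5L)
  expect_equal(unique(allele_resolution(call_f$combos[[1]], 5L)),
               "AA1*00101")
  # the initial stage distinguishes the sibling at non-coding positions
  call_i <- genotype_group(db, "AA1", frame, depth, copy = 2L,
                           scoring_params("initial"))
  expect_equal(call_i$resolution, 7L)
  expect_identical(call_i$combos, list(c(a, a)))
  expect_true(call_i$locked)
})

test_that("final-stage mismatches yield an unresolved genotype", {
  p <- scoring_params("final")
  snps <- data.frame(pos = 1:2, variants = c("A", "C"), depths = "30",
                     zygosity = 1L, total = 30)
  bases <- rbind("X*0010101" = c("A", "T"), "Y*0010101" = c("G", "T"))
  frame <- list(frame_len = 2L, exonic = c(TRUE, TRUE), offset = 0L,
                alleles = rownames(bases))
  sc <- score_combinations(snps, bases, copy = 1L, p)
  expect_equal(sc$score, 1)
  # through the full group call: depth supporting a variant no allele has
  fam <- mini_family()
  db <- fam$prepared
  fr <- group_frame(db, "AA1")
  a <- fr$alleles[1]
  seqa <- db$alleles$seq[db$alleles$allele == a]
  starts <- seq(1L, nchar(seqa) - 149L, by = 3L)
  # corrupt one exonic position in every read that covers it
  fe <- db$features[db$features$allele == a & db$features$feature == "exon_2", ]
  tgt <- fe$start + 25L
  reads <- substring(seqa, starts, starts + 149L)
  cover <- starts <= tgt & starts + 149L >= tgt
  reads[cover] <- vapply(which(cover), function(i) {
    off <- tgt - starts[i] + 1L
    r <- reads[i]
    b <- substr(r, off, off)
    alt <- setdiff(c("A", "C", "G", "T"), b)[1]
    substr(r, off, off) <- alt
    r
  }, "")
  names(reads) <- paste0("r", seq_along(reads), "/1")
  rec <- pick_primary(align_reads(reads, reference_sequences(db, fr$alleles),
                                  mode = "best", max_mm = 6L))
  depth <- build_depth_table(rec, reads, fr)
  call <- genotype_group(db, "AA1", fr, depth, copy = 2L, p)
  expect_equal(call$status, "unresolved")
  expect_gt(call$score, 0)
})

test_that("genotype formatting adds nulls, merges groups, orders ambiguity", {
  mk_call <- function(group, copy, combos, status = "resolved",
                      score = 0) {
    structure(list(group = group, copy = copy, combos = combos,
                   score = score, resolution = 5L, status = status,
                   locked = FALSE), class = "GenotypeCall")
  }
  calls <- list(
    A = mk_call("A", 1L, list("A*0010101")),
    B = mk_call("B", 0L, list()),
    L1 = mk_call("L1", 1L, list("L1*0010101")),
    L2 = mk_call("L2", 1L, list("L2*0020101")),
    C = mk_call("C", 2L, list(c("C*0010101", "C*0020101"),
                              c("C*0010101", "C*0030101")))
  )
  copies <- c(A = 1L, B = 0L, L1 = 1L, L2 = 1L, C = 2L)
  tab <- format_genotypes(calls, copies, merges = list(L = c("L1", "L2")))
  expect_equal(tab$genotype[tab$gene == "A"], "A*00101+null")
  expect_equal(tab$genotype[tab$gene == "B"], "null+null")
  expect_equal(tab$genotype[tab$gene == "L"], "L1*00101+L2*00201")
  # ambiguity renders as a sorted, delimited list, deterministically
  expect_equal(tab$genotype[tab$gene == "C"],
               "C*00101+C*00201|C*00101+C*00301")
  tab2 <- format_genotypes(calls, copies, merges = list(L = c("L1", "L2")))
  expect_identical(tab, tab2)
})
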