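# Synthetic family generation and truth-labeled read simulation.

test_that("family build is deterministic and hits identity targets", {
  cfg <- mini_family_config()
  fam1 <- suppressWarnings(build_family(cfg))
  fam2 <- suppressWarnings(build_family(cfg))
  expect_identical(fam1$db$alleles, fam2$db$alleles)
  # realized parent-child identity within 2 points of configured
  id <- family_identity(fam1)
  for (gs in cfg$genes) {
    if (!identical(gs$parent, "ancestor") && is.null(gs$mosaic)) {
      expect_lt(abs(id[gs$name, gs$parent] - (1 - gs$divergence)), 0.02)
    }
  }
  # infeasible identity constraints error
  bad <- cfg
  bad$genes[[2]]$divergence <- 1.4
  expect_error(suppressWarnings(build_family(bad)), "infeasible")
  # zero masking leaves all alleles fully characterized
  nomask <- cfg
  for (i in seq_along(nomask$genes)) nomask$genes[[i]]$mask_fraction <- 0
  fam0 <- suppressWarnings(build_family(nomask))
  expect_false(any(grepl("N", fam0$db$alleles$seq, fixed = TRUE)))
})

test_that("genotype sampling follows the templates", {
  fam <- mini_family()
  set.seed(1)
  tr <- sample_genotype(fam, "T")
  # framework present at two copies; copies equal allele multiset sizes
  expect_equal(unname(tr$copies[["FW1"]]), 2L)
  for (g in names(tr$alleles)) {
    expect_equal(length(tr$alleles[[g]]), unname(tr$copies[[g]]))
    expect_equal(length(unique(tr$alleles[[g]])),
                 length(tr$alleles[[g]]))
  }
  # no residual uncharacterized sequence after patching
  expect_false(any(grepl("N", tr$seqs, fixed = TRUE)))
  # copy distribution over many draws matches template-pair enumeration
  set.seed(2)
  draws <- replicate(400, sample_genotype(fam, "x")$copies["BB1"])
  tpl_bb <- vapply(fam$templates, function(t) {
    if ("BB1" %in% names(t)) t[["BB1"]] else 0L
  }, integer(1))
  grid <- expand.grid(a = tpl_bb, b = tpl_bb)
  expected <- table(factor(grid$a + grid$b, levels = 0:2)) / nrow(grid)
  observed <- table(factor(draws, levels = 0:2)) / length(draws)
  expect_lt(max(abs(observed - expected)), 0.08)
})

test_that("read simulation is deterministic, labeled and at coverage", {
  fam <- mini_family()
  set.seed(33)
  tr <- sample_genotype(fam, "S1")
  set.seed(44)
  rd1 <- simulate_reads(tr, fam$config)
  set.seed(44)
  rd2 <- simulate_reads(tr, fam$config)
  expect_identical(rd1, rd2)
  # names parse back to the truth alleles
  parsed <- parse_read_names(names(rd1$r1))
  expect_setequal(unique(parsed$allele), names(tr$seqs))
  expect_true(all(parsed$sample_id == "S1"))
  # per-allele depth near the 50x target (3 sigma by a binomial bound)
  a <- names(tr$seqs)[1]
  n <- sum(parsed$allele == a)
  len <- nchar(tr$seqs[[a]])
  depth <- n * 2 * fam$config$read_len / len
  expect_lt(abs(depth - fam$config$coverage),
            3 * sqrt(fam$config$coverage))
  # with the error model off, every read is a substring of its source
  cfg0 <- fam$config
  cfg0$error_rate <- c(0, 0)
  set.seed(45)
  rd0 <- simulate_reads(tr, cfg0)
  p0 <- parse_read_names(names(rd0$r1))
  hit <- mapply(function(r, a) {
    grepl(r, tr$seqs[[a]], fixed = TRUE) ||
      grepl(revcomp(r), tr$seqs[[a]], fixed = TRUE)
  }, rd0$r1[1:50], p0$allele[1:50])
  expect_true(all(hit))
})

test_that("cohort simulation writes paired FASTQ and a truth table", {
  fam <- mini_family()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  coh1 <- simulate_cohort(fam, 2L, seed = 5, dir = dir1)
  coh2 <- simulate_cohort(fam, 2L, seed = 5, dir = dir2)
  # byte-identical under the same seed
  for (i in 1:2) {
    expect_identical(readBin(coh1$manifest$fq1[i], "raw", 1e6),
                     readBin(coh2$manifest$fq1[i], "raw", 1e6))
  }
  r1 <- read_fastq(coh1$manifest$fq1[1])
  r2 <- read_fastq(coh1$manifest$fq2[1])
  expect_equal(length(r1), length(r2))
  expect_true(all(endsWith(names(r1), "/1")))
  # truth round-trip from read names
  parsed <- parse_read_names(names(r1))
  tr <- coh1$truth[["S01"]]
  expect_setequal(unique(parsed$allele),
                  unlist(tr$alleles, use.names = FALSE))
  counts <- table(parsed$gene)
  expect_setequal(names(counts), names(tr$copies[tr$copies > 0]))
})
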