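# Small programmatic fixtures shared across tests.

# hand-sized two-gene database: 3 alleles per gene, 60 bp alleles with a
# 5UTR / exon / intron / exon / 3UTR structure and one exons-only allele
make_toy_db <- function(seed = 5) {
  set.seed(seed)
  base_ga <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  base_gb <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  ga1 <- base_ga
  ga2 <- mut(base_ga, c(15, 45), c("A", "C")) # exonic differences
  ga2 <- mut(ga2, 15, if (substr(base_ga, 15, 15) == "A") "G" else "A")
  ga3 <- mut(base_ga, 35, if (substr(base_ga, 35, 35) == "T") "C" else "T")
  # exons-only characterization of ga3
  nonexon <- c(1:10, 31:40, 51:60)
  v <- strsplit(ga3, "")[[1]]; v[nonexon] <- "N"
  ga3 <- paste(v, collapse = "")
  gb1 <- base_gb
  gb2 <- mut(base_gb, 20, if (substr(base_gb, 20, 20) == "C") "T" else "C")
  gb3 <- mut(base_gb, c(12, 44), c("G", "G"))
  gb3 <- mut(gb3, 12, if (substr(base_gb, 12, 12) == "G") "T" else "G")
  alleles <- data.frame(
    allele = c("GA*0010101", "GA*0020101", "GA*0010201",
               "GB*0010101", "GB*0010102", "GB*0020101"),
    gene = rep(c("GA", "GB"), each = 3L),
    group = rep(c("GA", "GB"), each = 3L),
    seq = c(ga1, ga2, ga3, gb1, gb2, gb3),
    stringsAsFactors = FALSE)
  feats <- data.frame(
    allele = rep(alleles$allele, each = 5L),
    feature = rep(c("5UTR", "exon_1", "intron_1", "exon_2", "3UTR"), 6L),
    start = rep(c(0L, 10L, 30L, 40L, 50L), 6L),
    end = rep(c(10L, 30L, 40L, 50L, 60L), 6L),
    stringsAsFactors = FALSE)
  msas <- list(GA = setNames(alleles$seq[1:3], alleles$allele[1:3]),
               GB = setNames(alleles$seq[4:6], alleles$allele[4:6]))
  donors <- data.frame(
    gene = rep(c("GA", "GB"), each = 2L),
    group = rep(c("GA", "GB"), each = 2L),
    side = rep(c("5", "3"), 2L),
    seq = replicate(4, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = "")),
    stringsAsFactors = FALSE)
  allele_database(alleles, feats, msas, donors, framework = "GA")
}

# compact synthetic family for workflow-level tests: three genes plus
# framework, short features, fast to simulate
mini_family_config <- function(seed = 303L) {
  cfg <- family_config(seed)
  cfg$feature_lens <- c("5UTR" = 100L, exon_1 = 80L, intron_1 = 100L,
                        exon_2 = 100L, intron_2 = 100L, exon_3 = 80L,
                        "3UTR" = 150L)
  cfg$utr_target <- 250L
  gene <- function(name, parent, divergence, ...) {
    modifyList(list(name = name, parent = parent, divergence = divergence,
                    groups3 = 2L, per5 = 2L, extra7 = 1L,
                    allelic_div = 0.004, mask_fraction = 0.25,
                    mosaic = NULL),
               list(...))
  }
  cfg$genes <- list(
    gene("FW1", "ancestor", 0.20, mask_fraction = 0),
    gene("AA1", "ancestor", 0.22, mask_fraction = 0),
    gene("BB1", "ancestor", 0.18, mask_fraction = 0.3))
  cfg$templates <- list(
    T1 = c(FW1 = 1L, AA1 = 1L, BB1 = 1L),
    T2 = c(FW1 = 1L, AA1 = 1L),
    T3 = c(FW1 = 1L, BB1 = 1L))
  cfg$merges <- list()
  cfg
}

mini_family <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) fam <<- suppressWarnings(build_family(mini_family_config()))
    fam
  }
})

packaged_family <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) fam <<- suppressWarnings(build_family())
    fam
  }
})
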