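# Hand-built fixture shared by workflow and acceptance tests.
# Hand-built three-gene database for the adversarial fixture.
#   PP: P1/P2 differ only at 6 exonic positions in region R; P3 is a
#       distant group.  Truth is {P2,P2}.
#   QQ: Q2 equals Q1 outside region R'; inside R' Q2 carries P1's
#       sequence except two positions with a third base.  Truth {Q2,Q2}.
# With the initial reference restricted to P1/Q1, Q2's reads from R'
# misalign onto P1 (their own reference lacks them), seeding false
# heterozygous SNPs on PP and a mis-typing in round 1.
make_adversarial <- function() {
  set.seed(404)
  len <- 1200L
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  mut_at <- function(s, pos, shift = 1L) {
    v <- strsplit(s, "")[[1]]
    bases <- c("A", "C", "G", "T")
    v[pos] <- bases[(match(v[pos], bases) - 1L + shift) %% 4L + 1L]
    paste(v, collapse = "")
  }
  fw <- rand(len)
  p1 <- rand(len)
  r_pos <- c(181L, 221L, 251L, 281L, 311L, 341L) # inside exon_1 region R
  p2 <- mut_at(p1, r_pos)
  p3 <- mut_at(p1, seq(120L, 1080L, by = 60L), shift = 2L)
  q1 <- rand(len)
  # Q2: Q1 outside R' = [150, 350]; P1's sequence inside, third base at 2
  q2 <- paste0(substr(q1, 1, 149), substr(p1, 150, 350),
               substr(q1, 351, len))
  q2 <- mut_at(q2, c(221L, 311L), shift = 2L) # third base at two r_pos
  alleles <- data.frame(
    allele = c("FW*0010101", "PP*0010101", "PP*0010201", "PP*0020101",
               "QQ*0010101", "QQ*0010201"),
    gene = c("FW", "PP", "PP", "PP", "QQ", "QQ"),
    group = c("FW", "PP", "PP", "PP", "QQ", "QQ"),
    seq = c(fw, p1, p2, p3, q1, q2),
    stringsAsFactors = FALSE)
  feats <- data.frame(
    allele = rep(alleles$allele, each = 5L),
    feature = rep(c("5UTR", "exon_1", "intron_1", "exon_2", "3UTR"), 6L),
    start = rep(c(0L, 100L, 500L, 700L, 1100L), 6L),
    end = rep(c(100L, 500L, 700L, 1100L, 1200L), 6L),
    stringsAsFactors = FALSE)
  msas <- lapply(split(alleles, alleles$gene), function(d) {
    setNames(d$seq, d$allele)
  })
  donors <- data.frame(gene = character(), group = character(),
                       side = character(), seq = character())
  allele_database(alleles, feats, msas, donors, framework = "FW")
}

tile_reads <- function(db, allele, copies = 2L, step = 3L) {
  s <- db$alleles$seq[db$alleles$allele == allele]
  starts <- seq(1L, nchar(s) - 149L, by = step)
  reads <- rep(substring(s, starts, starts + 149L), copies)
  setNames(reads, paste0("t|", allele, "|",
                         seq_along(reads), "/1"))
}

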