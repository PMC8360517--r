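# 50-sample synthetic cohort processed by the full pipeline, computed
# once and shared by the acceptance-level tests.  The cohort replicates
# the packaged study conditions: haplotype-template genotypes, 150 bp
# paired-end reads at 50x, fragment median 200, fixed seed.

acceptance_cohort <- local({
  res <- NULL
  function(seed = 1234L, n = 50L) {
    if (!is.null(res)) return(res)
    fam <- suppressWarnings(build_family())
    dir <- file.path(tempdir(), "acceptance_cohort")
    coh <- simulate_cohort(fam, n, seed, dir)
    man <- pipeline_extract(coh$manifest, fam$haplotype_refs,
                            file.path(dir, "extracted"))
    cn <- suppressWarnings(
      pipeline_copy(man, fam$prepared, fam$minimized))
    comprehensive <- reference_set("comprehensive",
                                   fam$prepared$alleles$allele)
    cn_full <- suppressWarnings(
      pipeline_copy(man, fam$prepared, comprehensive))
    gt <- pipeline_genotype(man, cn$copies, fam$prepared, fam$minimized,
                            probes = fam$probes,
                            merges = fam$config$merges)
    res <<- list(fam = fam, coh = coh, man = man, cn = cn,
                 cn_full = cn_full, gt = gt)
    res
  }
})

# per-component five-digit genotype comparison for one gene across the
# cohort: returns matched / total and matched / resolved-total fractions
component_match_rates <- function(ac, gene) {
  truth <- ac$coh$truth
  runs <- ac$gt$runs
  total <- matched <- resolved_total <- resolved_matched <- 0L
  for (sid in names(truth)) {
    tr_all <- truth[[sid]]$alleles[[gene]]
    if (is.null(tr_all) || !length(tr_all)) next
    want <- sort(allele_resolution(tr_all, 5L))
    call <- runs[[sid]]$calls[[gene]]
    total <- total + length(want)
    got <- if (!is.null(call) && call$status == "resolved" &&
               length(call$combos)) {
      sort(allele_resolution(call$combos[[1]], 5L))
    } else NULL
    if (is.null(got)) next # unresolved: counts against the overall rate
    resolved_total <- resolved_total + length(want)
    m <- 0L
    w <- want
    for (g in got) {
      hit <- match(g, w)
      if (!is.na(hit)) { m <- m + 1L; w <- w[-hit] }
    }
    matched <- matched + m
    resolved_matched <- resolved_matched + m
  }
  list(match_rate = matched / total,
       resolved_rate = resolved_matched / resolved_total,
       n = total, n_resolved = resolved_total)
}

# off-target unique reads: reads classified unique to a group other than
# their truth source gene, summed over the cohort for a reference set
off_target_unique <- function(ac, refset, max_mm = 6L) {
  refs <- reference_sequences(ac$fam$prepared, refset)
  grouping <- setNames(ac$fam$prepared$alleles$group,
                       ac$fam$prepared$alleles$allele)
  total <- 0L
  for (i in seq_len(nrow(ac$man))) {
    r <- c(read_fastq(ac$man$fq1[i]), read_fastq(ac$man$fq2[i]))
    rec <- align_reads(r, refs, mode = "exhaustive", max_mm = max_mm)
    uc <- classify_unique(rec, grouping)
    rg <- uc$read_group[!is.na(uc$read_group$group)]
    src <- parse_read_names(rg$read)$gene
    total <- total + sum(src != rg$group)
  }
  total
}
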