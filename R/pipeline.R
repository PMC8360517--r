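# Pipeline orchestration: extraction -> copy number -> genotyping ->
# tracing over a batch of samples, with deterministic seeding and
# TSV/FASTQ artifacts per stage.

#' Extract a batch of samples
#'
#' @param manifest data.frame with `sample_id`, `fq1`, `fq2`.
#' @param haplotype_refs named character vector (or FASTA path) of
#'   haplotype references.
#' @param dir output directory for the extracted FASTQ pairs.
#' @param max_mm extractor mismatch cap.
#' @return updated manifest (extracted paths) with a `retention` column.
#' @export
pipeline_extract <- function(manifest, haplotype_refs, dir,
                             max_mm = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- manifest
  out$fq1 <- file.path(dir, paste0(manifest$sample_id, "_1.fastq.gz"))
  out$fq2 <- file.path(dir, paste0(manifest$sample_id, "_2.fastq.gz"))
  out$retention <- NA_real_
  for (i in seq_len(nrow(manifest))) {
    ex <- extract_reads(manifest$fq1[i], manifest$fq2[i], haplotype_refs,
                        max_mm = max_mm, out1 = out$fq1[i],
                        out2 = out$fq2[i])
    out$retention[i] <- ex$counts[["retention"]]
  }
  out
}

#' Copy-number stage over a batch
#'
#' Exhaustive alignment of every sample to the reference set, unique-read
#' classification per gene/major allelic group, ratio normalization
#' against the framework gene, automatic thresholding, and optional
#' complementary-pair fallback for flagged genes.
#'
#' @param manifest data.frame with `sample_id`, `fq1`, `fq2` (extracted
#'   reads).
#' @param db prepared `AlleleDatabase`.
#' @param refset `ReferenceSet` to align against (minimized for routine
#'   use, the comprehensive allele set for maximum unique-read
#'   discrimination).
#' @param max_mm genotyping alignment mismatch cap.
#' @param overrides named list of manual `CopyThresholds` per gene.
#' @param fallback_pairs list of `list(gene_a=, gene_b=, total=)`
#'   complementary-pair rules, applied when `gene_a` is flagged as
#'   poorly separable.
#' @param max_copy copy cap.
#' @return list with `counts`, `ratios` (`CopyRatioMatrix`), `copies`
#'   (samples x groups), `thresholds`, `flagged`.
#' @export
pipeline_copy <- function(manifest, db, refset, max_mm = 6L,
                          overrides = list(), fallback_pairs = list(),
                          max_copy = 4L) {
  refs <- reference_sequences(db, refset)
  grouping <- setNames(db$alleles$group, db$alleles$allele)
  groups <- sort(unique(grouping))
  counts <- matrix(0L, nrow(manifest), length(groups),
                   dimnames = list(manifest$sample_id, groups))
  for (i in seq_len(nrow(manifest))) {
    r1 <- read_fastq(manifest$fq1[i])
    r2 <- read_fastq(manifest$fq2[i])
    rec <- align_reads(c(r1, r2), refs, mode = "exhaustive",
                       max_mm = max_mm)
    uc <- classify_unique(rec, grouping)
    counts[i, names(uc$counts)] <- as.integer(uc$counts)
  }
  rm <- ratio_matrix(counts, db$framework)
  res <- batch_copy_calls(rm, max_copy = max_copy, overrides = overrides)
  for (fp in fallback_pairs) {
    if (fp$gene_a %in% res$flagged) {
      res$copies <- paired_gene_fallback(res$copies, fp$gene_a,
                                         fp$gene_b,
                                         total = fp$total %||% 2L)
    }
  }
  list(counts = counts, ratios = rm, copies = res$copies,
       thresholds = res$thresholds, flagged = res$flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotyping stage over a batch
#'
#' Runs the iterative genotype-matched workflow per sample.
#'
#' @param manifest data.frame with `sample_id`, `fq1`, `fq2` (extracted
#'   reads).
#' @param copies samples x groups copy matrix.
#' @param db prepared `AlleleDatabase`.
#' @param minimized minimized `ReferenceSet`.
#' @param probes optional probe table.
#' @param merges named list of allelic-group merges for output.
#' @param ... passed to [run_genotyping_workflow()].
#' @return list with `table` (long data.frame: sample_id, gene, copy,
#'   genotype, status, score) and `runs` (per-sample workflow results).
#' @export
pipeline_genotype <- function(manifest, copies, db, minimized,
                              probes = NULL, merges = list(), ...) {
  runs <- list()
  tabs <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    r1 <- read_fastq(manifest$fq1[i])
    r2 <- read_fastq(manifest$fq2[i])
    cp <- copies[sid, ]
    run <- run_genotyping_workflow(r1, r2, cp, db, minimized,
                                   probes = probes, ...)
    tab <- format_genotypes(run$calls, cp, merges)
    tab <- cbind(sample_id = sid, tab)
    runs[[sid]] <- run
    tabs[[sid]] <- tab
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  list(table = out, runs = runs)
}

#' Validate a pipeline configuration
#'
#' @param config list (or YAML path) with at least `seed`, `outdir` and
#'   `n_samples`; optional `family_seed`, `max_mm`, `stages`.
#' @return normalized configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  need <- c("seed", "outdir", "n_samples")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config lacks field(s): ", paste(miss, collapse = ", "))
  }
  config$family_seed <- config$family_seed %||% 1009L
  config$max_mm <- config$max_mm %||% 6L
  config$stages <- config$stages %||%
    c("simulate", "extract", "copy", "genotype", "trace")
  config
}

#' Run the full pipeline on a simulated cohort
#'
#' Builds the synthetic family, simulates the cohort, and runs
#' extraction, copy determination, genotyping and tracing, writing TSV
#' artifacts and a run manifest under `outdir`.  Byte-identical outputs
#' for identical configuration and seed.
#'
#' @param config see [validate_config()].
#' @return list with the stage results (`family`, `cohort`, `copy`,
#'   `genotype`, `trace`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  family <- build_family(family_config(config$family_seed))
  cohort <- simulate_cohort(family, config$n_samples,
                            derive_seed(config$seed, "cohort"),
                            file.path(config$outdir, "reads"))
  manifest <- pipeline_extract(cohort$manifest, family$haplotype_refs,
                               file.path(config$outdir, "extracted"))
  fallback <- lapply(names(family$config$merges), function(m) {
    pair <- family$config$merges[[m]]
    list(gene_a = pair[1], gene_b = pair[2], total = 2L)
  })
  cn <- pipeline_copy(manifest, family$prepared, family$minimized,
                      max_mm = config$max_mm,
                      fallback_pairs = fallback)
  gt <- pipeline_genotype(manifest, cn$copies, family$prepared,
                          family$minimized, probes = family$probes,
                          merges = family$config$merges,
                          max_mm = config$max_mm)
  grouping <- setNames(family$prepared$alleles$group,
                       family$prepared$alleles$allele)
  flows <- rbindlist(lapply(names(gt$runs), function(sid) {
    fl <- trace_flows(gt$runs[[sid]]$final_records, grouping)$flows
    if (nrow(fl)) cbind(sample_id = sid, fl) else NULL
  }))

  write.table(cn$counts, file.path(config$outdir, "unique_counts.tsv"),
              sep = "\t", quote = FALSE)
  write.table(cn$ratios$ratios, file.path(config$outdir, "ratios.tsv"),
              sep = "\t", quote = FALSE)
  write.table(cn$copies, file.path(config$outdir, "copies.tsv"),
              sep = "\t", quote = FALSE)
  write.table(gt$table, file.path(config$outdir, "genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(flows),
              file.path(config$outdir, "read_flows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(list(
    seed = config$seed, family_seed = config$family_seed,
    n_samples = config$n_samples, max_mm = config$max_mm,
    package_version = as.character(utils::packageVersion("paratype")))),
    file.path(config$outdir, "run_manifest.yaml"))

  list(family = family, cohort = cohort, extract = manifest, copy = cn,
       genotype = gt, trace = as.data.frame(flows))
}
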