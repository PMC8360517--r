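# The genotype-matched alignment workflow: a gene-content-matched
# exhaustive alignment seeds an initial genotype; two genotype-matched
# exhaustive rounds refine it, with perfect unambiguous typings locked
# in, a diverse-set injection for genes whose typing mismatches the
# aligned SNPs (anti-stuck), fully characterized sequence injection for
# genes represented only by partially characterized references, and
# probe-driven reference refinement; a final non-exhaustive round over
# all aligned reads yields the exonic-resolution genotype.

# group-restricted depth table from one round's records
group_depth <- function(records, reads, frame, unique_reads = NULL) {
  rec <- records[records$ref %in% frame$alleles]
  if (!is.null(unique_reads)) rec <- rec[rec$read %in% unique_reads]
  rec <- pick_primary(rec)
  build_depth_table(rec, reads, frame)
}

# reference alleles representing the current typing of one group
typing_alleles <- function(call) {
  unique(unlist(call$combos, use.names = FALSE))
}

#' Run the iterative genotype-matched workflow for one sample
#'
#' Stages: (1) exhaustive alignment to a gene-content-matched reference
#' drawn from the minimized set (groups at copy 0 excluded, the
#' framework gene always included), unique-read depth tables, initial
#' genotype; (2) `n_intermediate` genotype-matched exhaustive rounds:
#' the reference holds the current typings including ambiguity, perfect
#' unambiguous typings are locked for all later intermediate rounds,
#' groups whose typing mismatches the aligned SNPs additionally receive
#' the minimized diverse alleles, groups represented only by partially
#' characterized sequence receive their most complete minimized allele,
#' and probe refinement rules are applied; (3) final non-exhaustive
#' alignment to the locked plus most congruent typings, all aligned
#' reads processed, final-stage scoring.
#'
#' @param r1,r2 named character vectors of extracted mate sequences.
#' @param copies named integer vector: copy number per group.
#' @param db prepared (imputed, extended) `AlleleDatabase`.
#' @param minimized minimized `ReferenceSet`.
#' @param probes optional probe table for reference refinement.
#' @param n_intermediate number of genotype-matched rounds (default 2).
#' @param max_mm genotyping alignment mismatch cap (default 6).
#' @param initial_reference optional `ReferenceSet` overriding the
#'   gene-content-matched initial reference.
#' @return list with `calls` (final `GenotypeCall` per group), `table`
#'   (formatted genotypes, unmerged), `audit` (per-round reference,
#'   scores and lock events) and `final_records` (final-round primary
#'   placements, for tracing).
#' @export
run_genotyping_workflow <- function(r1, r2, copies, db, minimized,
                                    probes = NULL, n_intermediate = 2L,
                                    max_mm = 6L,
                                    initial_reference = NULL) {
  reads <- c(r1, r2)
  grouping <- setNames(db$alleles$group, db$alleles$allele)
  groups <- names(copies)
  stopifnot(all(groups %in% grouping))
  active <- groups[copies > 0L]
  frames <- lapply(setNames(active, active),
                   function(g) group_frame(db, g))

  minimized_of <- split(minimized$alleles,
                        allele_groups(db, minimized$alleles))
  comp <- completeness_report(db)
  hits <- if (!is.null(probes) && nrow(probes)) probe_hits(reads, probes)
          else NULL

  content_ref <- reference_set(
    "gene-content-matched",
    unlist(minimized_of[intersect(active, names(minimized_of))],
           use.names = FALSE))
  refset <- if (is.null(initial_reference)) content_ref
            else initial_reference

  locked <- list()    # group -> GenotypeCall locked in
  congruent <- list() # group -> best (least-mismatch) call across rounds
  audit <- list()
  params_init <- scoring_params("initial")

  run_round <- function(refset, round_label) {
    refs <- reference_sequences(db, refset)
    records <- align_reads(reads, refs, mode = "exhaustive",
                           max_mm = max_mm)
    uc <- classify_unique(records, grouping)
    calls <- list()
    for (g in active) {
      if (!is.null(locked[[g]])) {
        calls[[g]] <- locked[[g]]
        next
      }
      uniq <- uc$read_group$read[!is.na(uc$read_group$group) &
                                 uc$read_group$group == g]
      depth <- group_depth(records, reads, frames[[g]],
                           unique_reads = uniq)
      calls[[g]] <- genotype_group(db, g, frames[[g]], depth,
                                   copies[[g]], params_init)
    }
    audit[[round_label]] <<- list(
      reference = refset$alleles,
      scores = vapply(calls, `[[`, 0, "score"),
      locked = names(calls)[vapply(calls, `[[`, TRUE, "locked")])
    calls
  }

  update_state <- function(calls) {
    for (g in names(calls)) {
      call <- calls[[g]]
      if (is.null(congruent[[g]]) ||
          (!is.na(call$score) &&
           (is.na(congruent[[g]]$score) ||
            call$score < congruent[[g]]$score))) {
        congruent[[g]] <<- call
      }
      if (is.null(locked[[g]]) && isTRUE(call$locked)) {
        locked[[g]] <<- call
      }
    }
  }

  next_reference <- function(calls, label) {
    alleles <- character()
    for (g in active) {
      call <- if (!is.null(locked[[g]])) locked[[g]] else calls[[g]]
      sel <- typing_alleles(call)
      if (!length(sel)) sel <- minimized_of[[g]]
      # anti-stuck: a typing that mismatches its aligned SNPs gets the
      # five diverse minimized alleles added
      if (is.null(locked[[g]]) &&
          (is.na(call$score) || call$score > 0)) {
        sel <- union(sel, minimized_of[[g]])
      }
      # partially characterized representation gets a fully
      # characterized allele added
      sel_frac <- comp$frac_imputed[match(sel, comp$allele)]
      if (all(sel_frac < 1)) {
        pool <- minimized_of[[g]]
        best <- pool[which.max(comp$frac_imputed[match(pool,
                                                       comp$allele)])]
        sel <- union(sel, best)
      }
      alleles <- c(alleles, sel)
    }
    rs <- reference_set(label, alleles)
    if (!is.null(hits)) rs <- apply_refinement_rules(hits, rs, db)
    rs
  }

  # stage 1: initial genotype
  calls <- run_round(refset, "initial")
  update_state(calls)

  # stage 2: genotype-matched rounds
  for (i in seq_len(n_intermediate)) {
    refset <- next_reference(calls, paste0("genotype-matched-", i))
    calls <- run_round(refset, paste0("intermediate_", i))
    update_state(calls)
  }

  # stage 3: final non-exhaustive round over all aligned reads
  final_alleles <- character()
  for (g in active) {
    call <- if (!is.null(locked[[g]])) locked[[g]] else congruent[[g]]
    sel <- typing_alleles(call)
    if (!length(sel)) sel <- minimized_of[[g]]
    final_alleles <- c(final_alleles, sel)
  }
  final_ref <- reference_set("final", final_alleles)
  if (!is.null(hits)) final_ref <- apply_refinement_rules(hits, final_ref, db)
  refs <- reference_sequences(db, final_ref)
  records <- align_reads(reads, refs, mode = "best", max_mm = max_mm)
  primary <- pick_primary(records)
  params_final <- scoring_params("final")
  final_calls <- list()
  for (g in groups) {
    if (copies[[g]] == 0L) {
      final_calls[[g]] <- genotype_group(db, g, NULL, NULL, 0L,
                                         params_final)
      next
    }
    depth <- group_depth(primary, reads, frames[[g]])
    final_calls[[g]] <- genotype_group(db, g, frames[[g]], depth,
                                       copies[[g]], params_final)
  }
  audit[["final"]] <- list(reference = final_ref$alleles,
                           scores = vapply(final_calls, `[[`, 0, "score"),
                           locked = names(locked))
  list(calls = final_calls,
       table = format_genotypes(final_calls, copies),
       audit = audit,
       final_records = primary)
}
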