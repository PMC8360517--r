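# Virtual sequence probes: short sequences unique to a target allele or
# allelic group, detected by exact substring matching in the raw reads.
# Probe hits flag presence of alleles prone to misidentification and
# drive reference-refinement rules during the genotyping workflow.

#' Count distinct reads containing a probe
#'
#' Exact substring match against each read or its reverse complement
#' (raw FASTQ strand is arbitrary); duplicate read sequences count once.
#'
#' @param reads character vector of read sequences.
#' @param probe probe sequence (20-50 nt over ACGT).
#' @return integer count of distinct matching read sequences.
#' @export
count_probe <- function(reads, probe) {
  if (!nchar(probe)) stop("empty probe sequence")
  if (grepl("[^ACGT]", probe)) stop("probe must be over A, C, G, T")
  u <- unique(unname(reads))
  sum(stringi::stri_detect_fixed(u, probe) |
      stringi::stri_detect_fixed(u, revcomp(probe)))
}

#' Probe hit calls for a probe table
#'
#' @param reads character vector of read sequences.
#' @param probes probe table (see [read_probe_table()]).
#' @return the probe table with `count` and `hit` columns appended
#'   (`hit` when `count >= threshold`).
#' @export
probe_hits <- function(reads, probes) {
  probes$count <- vapply(probes$sequence, function(p) count_probe(reads, p),
                         integer(1), USE.NAMES = FALSE)
  probes$hit <- probes$count >= probes$threshold
  probes
}

#' Verify that a probe is unique to its declared targets
#'
#' Scans every (imputed, extended) allele sequence of the database for
#' exact containment of the probe (either strand) and reports all
#' carriers; the probe passes iff carriers are confined to the declared
#' target set.
#'
#' @param probe probe sequence.
#' @param db an `AlleleDatabase`.
#' @param targets character vector of allele names the probe is allowed
#'   to match.
#' @return list with `carriers` (allele names containing the probe),
#'   `off_target` and `pass`.
#' @export
verify_probe_uniqueness <- function(probe, db, targets) {
  if (!nchar(probe)) stop("empty probe sequence")
  hit <- stringi::stri_detect_fixed(db$alleles$seq, probe) |
         stringi::stri_detect_fixed(db$alleles$seq, revcomp(probe))
  carriers <- db$alleles$allele[hit]
  off <- setdiff(carriers, targets)
  list(carriers = carriers, off_target = off, pass = length(off) == 0L)
}

#' Design a probe unique to a target allele set
#'
#' Searches windows of the first target allele for a substring contained
#' in every target allele and in no other allele of the database.
#' Returns `NA` when no such window exists.
#'
#' @param db an `AlleleDatabase`.
#' @param targets character vector of target allele names.
#' @param length probe length (default 40).
#' @return probe sequence or `NA_character_`.
#' @export
design_probe <- function(db, targets, length = 40L) {
  stopifnot(length(targets) > 0L)
  s <- db$alleles$seq[db$alleles$allele == targets[1L]]
  n <- nchar(s) - length + 1L
  for (start in seq(1L, n, by = 7L)) {
    cand <- substr(s, start, start + length - 1L)
    if (grepl("N", cand, fixed = TRUE)) next
    v <- verify_probe_uniqueness(cand, db, targets)
    if (v$pass && all(targets %in% v$carriers)) return(cand)
  }
  NA_character_
}

#' Read a probe table
#'
#' TSV schema: `name`, `target`, `sequence`, `threshold`, `action`
#' (`presence_flag` or `add_reference_allele`), `action_arg` (allele to
#' add), `precedence_group`, `precedence` (1 = dominant within its
#' group).  Probe tables are data, not code: family-specific probes plug
#' in without code changes.
#'
#' @param path TSV path.
#' @return probe data.frame.
#' @export
read_probe_table <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "target", "sequence", "threshold", "action")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("probe table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(p$precedence_group)) p$precedence_group <- p$name
  if (is.null(p$precedence)) p$precedence <- 1L
  if (is.null(p$action_arg)) p$action_arg <- NA_character_
  p
}

#' Apply reference-refinement rules from probe hits
#'
#' For each firing `add_reference_allele` rule the named allele joins the
#' reference (deduplicated).  Within a precedence group, when more than
#' one rule fires only the dominant rule's allele is added, overriding
#' the individual additions.  Applying the rules twice equals applying
#' them once.
#'
#' @param hits probe table with `hit` column (see [probe_hits()]).
#' @param reference a `ReferenceSet`.
#' @param db an `AlleleDatabase` (validates rule allele names).
#' @return the refined `ReferenceSet`.
#' @export
apply_refinement_rules <- function(hits, reference, db) {
  rules <- hits[hits$action == "add_reference_allele", , drop = FALSE]
  unknown <- setdiff(rules$action_arg, db$alleles$allele)
  if (length(unknown)) {
    stop("refinement rule names unknown allele(s): ",
         paste(unknown, collapse = ", "))
  }
  add <- character()
  for (grp in unique(rules$precedence_group)) {
    sub <- rules[rules$precedence_group == grp & rules$hit, , drop = FALSE]
    if (!nrow(sub)) next
    if (nrow(sub) > 1L) {
      dom <- rules[rules$precedence_group == grp, , drop = FALSE]
      dom <- dom[order(dom$precedence), ]
      add <- c(add, dom$action_arg[1L])
    } else {
      add <- c(add, sub$action_arg)
    }
  }
  reference_set(reference$label,
                union(reference$alleles, add))
}
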