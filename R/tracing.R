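# Misaligned-read tracing: with truth-labeled reads (names encoding the
# source allele), reads landing on a different gene/major allelic group
# than their source are tabulated pairwise, source x aligned.

#' Trace read flows between source and aligned genes
#'
#' @param records `AlignmentRecords` (typically one placement per read,
#'   e.g. the final-round primary placements).
#' @param grouping named character vector mapping reference allele ->
#'   group.
#' @param scope `"all"` tabulates flows for every group;
#'   `"discordant"` restricts to the given `discordant_groups`.
#' @param discordant_groups groups to keep when `scope = "discordant"`
#'   (the incorrectly genotyped genes).
#' @return list with `flows` (data.frame source_gene, aligned_group,
#'   reads; off-target placements only), `on_target` (named counts),
#'   `skipped` (reads with unparseable names).
#' @export
trace_flows <- function(records, grouping,
                        scope = c("all", "discordant"),
                        discordant_groups = character()) {
  scope <- match.arg(scope)
  truth <- parse_read_names(records$read)
  skipped <- sum(is.na(truth$allele))
  ok <- !is.na(truth$allele)
  dt <- data.table(source_gene = truth$gene[ok],
                   aligned_group = unname(grouping[records$ref[ok]]))
  if (scope == "discordant") {
    dt <- dt[aligned_group %in% discordant_groups]
  }
  on_target <- dt[source_gene == aligned_group,
                  list(reads = .N), by = source_gene]
  flows <- dt[source_gene != aligned_group,
              list(reads = .N), by = list(source_gene, aligned_group)]
  setorder(flows, source_gene, aligned_group)
  list(flows = as.data.frame(flows),
       on_target = setNames(on_target$reads, on_target$source_gene),
       skipped = skipped)
}
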