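# Alignment backend: exhaustive / best-placement read alignment against a
# reference allele set, unique-read classification by gene or major
# allelic group, projection of placements onto a per-group coordinate
# frame, and depth-table construction.
#
# The built-in aligner is a seeded ungapped matcher (pigeonhole seeding,
# mismatch cap, 'N' reference positions match any base at no penalty).
# A SAM adapter provides interoperability with external aligners.

#' Align reads to a reference set
#'
#' In `exhaustive` mode every placement meeting the mismatch cap is
#' recorded for each read; in `best` mode only the minimum-mismatch
#' placement(s).  Reference `N` positions match any base at zero
#' penalty.  Both strands are searched.
#'
#' @param reads named character vector of read sequences.
#' @param refs named character vector of reference sequences.
#' @param mode `"exhaustive"` or `"best"`.
#' @param max_mm mismatch cap per read (default 6 per 150 bp read).
#' @param seed_len seed length for the index; the default derives from
#'   the pigeonhole bound `floor(min_read_len / (max_mm + 1))` (capped at
#'   31), which guarantees that no qualifying placement is missed across
#'   fully characterized reference windows.
#' @return an `AlignmentRecords` data.table with columns `read` (name),
#'   `ref` (reference name), `pos` (0-based offset), `strand`
#'   (`"+"`/`"-"`) and `nmis`.
#' @export
align_reads <- function(reads, refs, mode = c("exhaustive", "best"),
                        max_mm = 6L, seed_len = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(refs) > 0L)
  if (!length(reads)) {
    return(data.table(read = character(), ref = character(),
                      pos = integer(), strand = character(),
                      nmis = integer()))
  }
  if (is.null(seed_len)) {
    seed_len <- min(31L, max(8L, min(nchar(reads)) %/% (max_mm + 1L)))
  }
  hits <- cpp_align(unname(reads), unname(refs), as.integer(max_mm),
                    as.integer(seed_len), mode == "exhaustive", TRUE)
  out <- data.table(
    read = names(reads)[hits$read],
    ref = names(refs)[hits$ref],
    pos = hits$pos,
    strand = c("+", "-")[hits$strand + 1L],
    nmis = hits$nmis,
    read_idx = hits$read)
  setorder(out, read_idx, ref, pos, strand)
  out[, read_idx := NULL]
  out[]
}

#' Keep one primary placement per read
#'
#' Deterministic tie-break among minimum-mismatch placements:
#' lexicographic reference name, then position, then strand.
#'
#' @param records output of [align_reads()].
#' @return records with a single row per read.
#' @export
pick_primary <- function(records) {
  if (!nrow(records)) return(records)
  rec <- records[order(read, nmis, ref, pos, strand)]
  rec[!duplicated(rec$read)]
}

#' Classify reads as unique to a gene/major allelic group
#'
#' A read is unique to group G when every recorded placement of the read
#' lies on alleles of G; reads with placements in more than one group are
#' cross-mapping.  Unique sets and the cross-mapping set partition the
#' aligned reads.
#'
#' @param records output of [align_reads()].
#' @param grouping named character vector mapping reference allele name
#'   to its group.
#' @return list with `read_group` (data.table read/group, group `NA` for
#'   cross-mapping reads), `counts` (named unique-read counts per group)
#'   and `cross` (character vector of cross-mapping read names).
#' @export
classify_unique <- function(records, grouping) {
  if (anyNA(grouping[unique(records$ref)])) {
    stop("grouping lacks reference allele(s): ",
         paste(setdiff(unique(records$ref), names(grouping)),
               collapse = ", "))
  }
  if (!nrow(records)) {
    return(list(read_group = data.table(read = character(),
                                        group = character()),
                counts = table(factor(character(),
                                      levels = unique(grouping))),
                cross = character()))
  }
  rec <- data.table(read = records$read,
                    group = unname(grouping[records$ref]))
  rg <- rec[, list(n_groups = data.table::uniqueN(group),
                   group = group[1L]), by = read]
  rg[n_groups > 1L, group := NA_character_]
  counts <- table(factor(rg$group, levels = sort(unique(grouping))))
  list(read_group = rg[, list(read, group)],
       counts = counts,
       cross = rg$read[is.na(rg$group)])
}

#' Per-group coordinate frame
#'
#' Builds the coordinate frame of a gene/major allelic group: target UTR
#' padding, the gene's MSA columns, and 3' padding.  Returns, per allele,
#' the map from allele position to frame position, plus frame-level exon
#' annotation (from the group's most complete allele) and the frame
#' offset such that `frame position 1` corresponds to
#' `-(pad5)` relative to the native gene start.
#'
#' @param db extended `AlleleDatabase`.
#' @param group group label.
#' @return list with `frame_len`, `offset`, `exonic` (logical per frame
#'   position), `maps` (named list of integer vectors, allele position ->
#'   frame position, `NA` where an allele has no base at a frame column).
#' @export
group_frame <- function(db, group) {
  al <- db$alleles[db$alleles$group == group, , drop = FALSE]
  if (!nrow(al)) stop("unknown group: ", group)
  gene <- al$gene[1L]
  rows <- db$msas[[gene]][al$allele]
  n_cols <- nchar(rows[[1L]])
  pad5 <- unique(al$pad5)
  pad3 <- unique(al$pad3)
  stopifnot(length(pad5) == 1L, length(pad3) == 1L)
  frame_len <- pad5 + n_cols + pad3
  maps <- lapply(seq_len(nrow(al)), function(i) {
    chars <- seq_chars(rows[[al$allele[i]]])[[1]]
    col_of <- which(chars != "-") # MSA column of each native base
    c(seq_len(pad5), pad5 + col_of, pad5 + n_cols + seq_len(pad3))
  })
  names(maps) <- al$allele
  # exon annotation from the most complete allele, projected to frame
  comp <- completeness_report(db)
  best <- al$allele[which.max(comp$frac_imputed[match(al$allele,
                                                      comp$allele)])]
  fe <- db$features[db$features$allele == best, , drop = FALSE]
  exonic <- logical(frame_len)
  m <- maps[[best]]
  for (k in which(grepl("^exon", fe$feature))) {
    span <- seq.int(fe$start[k] + 1L, fe$end[k])
    exonic[m[span]] <- TRUE
  }
  list(frame_len = frame_len, offset = -pad5, exonic = exonic,
       maps = maps, alleles = al$allele)
}

#' Build a depth table for one group
#'
#' Projects the given placements onto the group coordinate frame and
#' counts, per frame position, the aligned read bases for each of A, C,
#' G, T (deletion and insertion rows are carried for interface
#' completeness; the built-in ungapped aligner never emits them).
#' Placements whose reads extend outside the frame are clipped and the
#' dropped bases counted.
#'
#' @param records `AlignmentRecords` restricted to the placements to
#'   count (e.g. one placement per read).
#' @param reads named character vector of read sequences.
#' @param frame output of [group_frame()].
#' @return a `DepthTable`: list with `group` counts matrix (6 x
#'   frame_len, rows A,C,G,T,del,ins), `offset`, `exonic`.
#' @export
build_depth_table <- function(records, reads, frame) {
  counts <- matrix(0L, 6L, frame$frame_len,
                   dimnames = list(c("A", "C", "G", "T", "del", "ins"),
                                   NULL))
  rec <- records[records$ref %in% frame$alleles, , drop = FALSE]
  if (nrow(rec)) {
    oriented <- reads[rec$read]
    rev <- rec$strand == "-"
    oriented[rev] <- revcomp(oriented[rev])
    # allele position -> frame position; ungapped placements are
    # contiguous on the allele, so the frame start fully determines the
    # projection when the allele map is itself contiguous over the read
    start_frame <- vapply(seq_len(nrow(rec)), function(i) {
      frame$maps[[rec$ref[i]]][rec$pos[i] + 1L]
    }, integer(1))
    m <- cpp_depth(frame$frame_len, start_frame - 1L, unname(oriented))
    counts[1:4, ] <- counts[1:4, ] + m
  }
  structure(list(counts = counts, offset = frame$offset,
                 exonic = frame$exonic), class = "DepthTable")
}

#' @export
print.DepthTable <- function(x, ...) {
  cat(sprintf("DepthTable: %d positions (offset %d), total depth %.0f\n",
              ncol(x$counts), x$offset, sum(x$counts)))
  invisible(x)
}

#' Write alignment records as SAM
#'
#' Minimal SAM emission (ungapped placements, full-length match CIGAR,
#' NM tag) for interoperability with downstream tools.
#'
#' @param records `AlignmentRecords`.
#' @param reads named character vector of read sequences.
#' @param refs named character vector of reference sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reads, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs)))
  body <- character()
  if (nrow(records)) {
    seq <- reads[records$read]
    rev <- records$strand == "-"
    seq[rev] <- revcomp(seq[rev])
    flag <- ifelse(rev, 16L, 0L)
    body <- paste(records$read, flag, records$ref, records$pos + 1L,
                  255L, paste0(nchar(seq), "M"), "*", 0L, 0L, seq, "*",
                  paste0("NM:i:", records$nmis), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from SAM
#'
#' Adapter for external aligners: accepts ungapped (single `M` CIGAR)
#' alignments and converts them to `AlignmentRecords`.
#'
#' @param path SAM file.
#' @return list with `records` and `reads` (sequences recovered from the
#'   SAM, reoriented to the original read strand).
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) {
    return(list(records = data.table(read = character(), ref = character(),
                                     pos = integer(), strand = character(),
                                     nmis = integer()),
                reads = character()))
  }
  f <- data.table::tstrsplit(ln, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  if (any(!grepl("^[0-9]+M$", f[[6]]))) {
    stop("SAM adapter accepts ungapped (single-M CIGAR) records only")
  }
  nm <- rep(NA_integer_, length(ln))
  nm_m <- regmatches(ln, regexpr("NM:i:[0-9]+", ln))
  nm[grepl("NM:i:", ln)] <- as.integer(sub("NM:i:", "", nm_m))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seqs <- f[[10]]
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  records <- data.table(read = f[[1]], ref = f[[3]],
                        pos = as.integer(f[[4]]) - 1L,
                        strand = strand, nmis = nm)
  reads <- seqs[!duplicated(f[[1]])]
  names(reads) <- f[[1]][!duplicated(f[[1]])]
  list(records = records, reads = reads)
}
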