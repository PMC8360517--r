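# Truth-labeled synthetic data: a copy-variable, highly homologous gene
# family with partially characterized alleles, gene-content haplotype
# templates, and a paired-end short-read simulator whose read names
# encode the source allele so misaligned reads can be traced.

#' Default synthetic family configuration
#'
#' The packaged study design: an eleven-gene family built from a common
#' ancestor with pairwise identities spanning the 50-95% homology range,
#' including a framework gene (`FW1`, assumed two copies per sample and
#' used as the depth normalizer), a presence/absence-variable
#' low-homology gene (`PA1`), a fully characterized distinct-sequence
#' gene (`DS1`), a high-homology gene pair (`HH1`/`HH2`, ~97% identity),
#' two allelic-group pairs treated as independent genes but merged in
#' output (`GL1`/`GL2`, `GS1`/`GS2`; every haplotype carries exactly one
#' of `GL1`/`GL2`), a pseudogene analog (`PS1`) assembled as a mosaic of
#' `HH1` and `GS1` blocks around a short private segment so that it
#' shares the large majority of its 150-mers with its neighbors, and a
#' gene with half its alleles characterized for exons only (`XA1`).
#' Eight haplotype templates provide gene absence and duplication;
#' two templates drawn with replacement define each sample.
#'
#' Reads are 150 bp paired-end at 50x coverage with fragment length
#' median 200 (sd 30) and a position-ramped substitution error rate of
#' 0.2-0.6%.
#'
#' @param seed integer seed fixing the family structure (sequences,
#'   allele content, masking).  The default is the packaged family.
#' @return a list of configuration values consumed by [build_family()].
#' @export
family_config <- function(seed = 1009L) {
  feature_lens <- c("5UTR" = 250L, exon_1 = 90L, intron_1 = 140L,
                    exon_2 = 120L, intron_2 = 160L, exon_3 = 150L,
                    intron_3 = 130L, exon_4 = 120L, "3UTR" = 500L)
  gene <- function(name, parent, divergence, groups3 = 2L, per5 = 2L,
                   extra7 = 1L, allelic_div = 0.004, mask_fraction = 0.25,
                   mosaic = NULL, conversion = NULL) {
    list(name = name, parent = parent, divergence = divergence,
         groups3 = groups3, per5 = per5, extra7 = extra7,
         allelic_div = allelic_div, mask_fraction = mask_fraction,
         mosaic = mosaic, conversion = conversion)
  }
  tpl <- function(...) {
    x <- c(...)
    storage.mode(x) <- "integer"
    x
  }
  list(
    seed = as.integer(seed),
    feature_lens = feature_lens,
    utr_target = 1000L,
    genes = list(
      gene("FW1", "ancestor", 0.15),
      gene("PA1", "ancestor", 0.17),
      gene("DS1", "ancestor", 0.20, groups3 = 3L, extra7 = 2L,
           mask_fraction = 0),
      gene("HH1", "ancestor", 0.10),
      gene("HH2", "HH1", 0.03,
           conversion = list(from = "GL1", start = 301L, len = 250L)),
      gene("GL1", "ancestor", 0.12),
      gene("GL2", "GL1", 0.04),
      gene("GS1", "ancestor", 0.13),
      gene("GS2", "GS1", 0.05),
      gene("XA1", "ancestor", 0.11, mask_fraction = 0.5),
      gene("PS1", NA, NA, groups3 = 1L, per5 = 2L, extra7 = 0L,
           mask_fraction = 0,
           mosaic = list(
             list(from = "HH1", start = 1L, end = 1750L),
             list(from = "private", start = 1751L, end = 1900L),
             list(from = "GS1", start = 1901L, end = 2910L)))
    ),
    framework = "FW1",
    templates = list(
      T1 = tpl(FW1 = 1, PA1 = 1, DS1 = 1, HH1 = 1, HH2 = 1, GL1 = 1,
               GS1 = 1, PS1 = 1, XA1 = 1),
      T2 = tpl(FW1 = 1, PA1 = 1, DS1 = 1, HH1 = 1, GL2 = 1, GS2 = 1,
               PS1 = 1, XA1 = 1),
      T3 = tpl(FW1 = 1, DS1 = 1, HH2 = 1, GL1 = 1, GS1 = 1, XA1 = 1),
      T4 = tpl(FW1 = 1, PA1 = 1, DS1 = 1, HH1 = 1, GL2 = 1, GS1 = 1,
               PS1 = 1, XA1 = 1),
      T5 = tpl(FW1 = 1, DS1 = 1, HH1 = 1, HH2 = 2, GL1 = 1, GS2 = 1,
               PS1 = 1, XA1 = 1),
      T6 = tpl(FW1 = 1, PA1 = 1, DS1 = 1, HH2 = 1, GL2 = 1, GS2 = 1,
               XA1 = 1),
      T7 = tpl(FW1 = 1, DS1 = 1, HH1 = 1, GL1 = 1, GS1 = 1, PS1 = 1,
               XA1 = 1),
      T8 = tpl(FW1 = 1, PA1 = 1, DS1 = 1, HH1 = 1, HH2 = 1, GL1 = 1,
               GS2 = 1, PS1 = 1)
    ),
    merges = list(GL = c("GL1", "GL2"), GS = c("GS1", "GS2")),
    read_len = 150L,
    coverage = 50,
    frag_median = 200,
    frag_sd = 30,
    error_rate = c(0.002, 0.006),
    n_forced_exonic = 3L,
    n_5digit_exonic = 2L,
    n_7digit_noncoding = 2L
  )
}

# substitute `n` positions drawn from `pool` (1-based), avoiding `used`;
# returns list(seq, positions)
mutate_at <- function(seq, n, pool, used = integer()) {
  pool <- setdiff(pool, used)
  n <- min(n, length(pool))
  if (n == 0L) return(list(seq = seq, positions = integer()))
  pos <- sort(sample(pool, n))
  cur <- bases_at(seq, pos)
  shift <- sample(3L, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  new <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
  list(seq = sub_positions(seq, pos, new), positions = pos)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the synthetic gene family
#'
#' Generates gene sequences from a common ancestor (or as mosaics of
#' other genes), per-gene allele series with 3/5/7-digit naming semantics
#' (3-digit groups differ at several exonic positions, 5-digit variants
#' at additional exonic positions, 7-digit variants only at non-coding
#' positions), applies exons-only masking to a configured fraction of
#' alleles, and assembles the native allele database together with donor
#' UTR sequences, gene-content haplotype templates, haplotype reference
#' sequences for read extraction, and a reference-refinement probe table.
#'
#' The returned family also carries the preprocessed database
#' (`$prepared`: imputed and UTR-extended) and the minimized reference
#' set, ready for the pipeline stages.  Deterministic given the
#' configuration seed.
#'
#' @param config configuration list from [family_config()].
#' @return a `SyntheticFamily` object.
#' @export
build_family <- function(config = family_config()) {
  set.seed(config$seed)
  fl <- config$feature_lens
  native_len <- sum(fl)
  pad5_ctx <- config$utr_target - fl[["5UTR"]]
  pad3_ctx <- config$utr_target - fl[["3UTR"]]
  ctx_len <- pad5_ctx + native_len + pad3_ctx
  native_range <- c(pad5_ctx + 1L, pad5_ctx + native_len)

  # feature intervals in native allele coordinates (0-based half-open)
  ends <- cumsum(fl)
  starts <- c(0L, ends[-length(ends)])
  feat_tbl <- data.frame(feature = names(fl), start = unname(starts),
                         end = unname(ends), stringsAsFactors = FALSE)
  exon_pos <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                            feat_tbl$start[grepl("^exon", feat_tbl$feature)],
                            feat_tbl$end[grepl("^exon", feat_tbl$feature)],
                            SIMPLIFY = FALSE))
  noncoding_pos <- setdiff(seq_len(native_len), exon_pos)

  ancestor <- random_dna(ctx_len)
  contexts <- list()
  for (gs in config$genes) {
    if (!is.null(gs$mosaic)) {
      ctx <- vapply(gs$mosaic, function(b) {
        if (b$from == "private") random_dna(b$end - b$start + 1L)
        else substr(contexts[[b$from]], b$start, b$end)
      }, character(1))
      contexts[[gs$name]] <- paste(ctx, collapse = "")
      stopifnot(nchar(contexts[[gs$name]]) == ctx_len)
      next
    }
    if (gs$divergence < 0 || gs$divergence > 1) {
      stop("infeasible divergence for gene ", gs$name)
    }
    base <- if (identical(gs$parent, "ancestor")) ancestor
            else contexts[[gs$parent]]
    if (is.null(base)) stop("unknown parent for gene ", gs$name)
    contexts[[gs$name]] <-
      mutate_at(base, round(gs$divergence * ctx_len),
                seq_len(ctx_len))$seq
  }

  alleles <- list()
  features <- list()
  msas <- list()
  for (gs in config$genes) {
    gref <- substr(contexts[[gs$name]], native_range[1], native_range[2])
    used <- integer() # positions already spent on allelic differences
    seqs <- character()
    # mosaic (pseudogene) alleles vary only inside the private segment,
    # preserving the shared-k-mer structure of the copied blocks
    exon_pool <- exon_pos
    any_pool <- seq_len(native_len)
    n5 <- config$n_5digit_exonic
    if (!is.null(gs$mosaic)) {
      priv <- unlist(lapply(gs$mosaic, function(b) {
        if (b$from == "private") seq.int(b$start, b$end) else integer()
      })) - pad5_ctx
      any_pool <- priv[priv >= 1L & priv <= native_len]
      exon_pool <- intersect(exon_pos, any_pool)
      n5 <- 1L
    }
    for (g3 in seq_len(gs$groups3)) {
      if (g3 == 1L) {
        founder <- gref
      } else {
        m1 <- mutate_at(gref, config$n_forced_exonic, exon_pool, used)
        used <- c(used, m1$positions)
        m2 <- mutate_at(m1$seq, rpois(1L, gs$allelic_div * native_len),
                        any_pool, used)
        used <- c(used, m2$positions)
        founder <- m2$seq
        # gene-conversion allele group: a block of another gene's
        # sequence replaces this founder's (sequestration-prone alleles
        # whose reads misalign under single-sequence references)
        cv <- gs$conversion
        if (!is.null(cv) && g3 == 2L) {
          donor_nat <- substr(contexts[[cv$from]], native_range[1],
                              native_range[2])
          substr(founder, cv$start, cv$start + cv$len - 1L) <-
            substr(donor_nat, cv$start, cv$start + cv$len - 1L)
        }
      }
      for (g5 in seq_len(gs$per5)) {
        if (g5 == 1L) {
          v <- founder
        } else {
          m <- mutate_at(founder, n5, exon_pool, used)
          used <- c(used, m$positions)
          v <- m$seq
        }
        seqs[sprintf("%s*%03d%02d%02d", gs$name, g3, g5, 1L)] <- v
      }
    }
    if (gs$extra7 > 0L) {
      base_names <- head(names(seqs), gs$extra7)
      for (nm in base_names) {
        m <- mutate_at(seqs[[nm]], config$n_7digit_noncoding,
                       noncoding_pos, used)
        used <- c(used, m$positions)
        sib <- sub("01$", "02", nm)
        seqs[sib] <- m$seq
      }
    }
    # exons-only masking of a configured fraction (never the first allele)
    n_mask <- round(gs$mask_fraction * length(seqs))
    if (n_mask > 0L) {
      maskable <- names(seqs)[-1L]
      to_mask <- sample(maskable, min(n_mask, length(maskable)))
      for (nm in to_mask) {
        seqs[nm] <- sub_positions(seqs[[nm]], noncoding_pos, "N")
      }
    }
    alleles[[gs$name]] <- data.frame(
      allele = names(seqs), gene = gs$name, group = gs$name,
      seq = unname(seqs), stringsAsFactors = FALSE)
    features[[gs$name]] <- data.frame(
      allele = rep(names(seqs), each = nrow(feat_tbl)),
      feature = rep(feat_tbl$feature, length(seqs)),
      start = rep(feat_tbl$start, length(seqs)),
      end = rep(feat_tbl$end, length(seqs)), stringsAsFactors = FALSE)
    msas[[gs$name]] <- seqs # substitution-only family: gap-free MSA
  }

  donors <- do.call(rbind, lapply(names(contexts), function(g) {
    data.frame(gene = g, group = g, side = c("5", "3"),
               seq = c(substr(contexts[[g]], 1L, config$utr_target),
                       substr(contexts[[g]], ctx_len - config$utr_target +
                                             1L, ctx_len)),
               stringsAsFactors = FALSE)
  }))

  db <- allele_database(do.call(rbind, alleles), do.call(rbind, features),
                        msas, donors, config$framework)
  prepared <- extend_utrs(impute_database(db), config$utr_target)

  # haplotype references for the extractor: gene contexts joined by
  # random spacers, one reference per template
  hap_refs <- vapply(config$templates, function(tp) {
    genes <- rep(names(tp), tp)
    paste(vapply(genes, function(g) contexts[[g]], character(1)),
          collapse = random_dna(100L))
  }, character(1))

  fam <- structure(list(
    config = config, db = db, prepared = prepared,
    templates = config$templates, haplotype_refs = hap_refs,
    contexts = contexts
  ), class = "SyntheticFamily")
  fam$minimized <- select_minimized_reference(prepared)
  fam$probes <- design_family_probes(fam)
  fam
}

#' @export
print.SyntheticFamily <- function(x, ...) {
  cat(sprintf(
    "SyntheticFamily: %d genes, %d alleles, %d haplotype templates\n",
    length(unique(x$db$alleles$gene)), nrow(x$db$alleles),
    length(x$templates)))
  invisible(x)
}

# Reference-refinement probe table for the family, mirroring the probe
# precedence semantics used for alleles prone to misidentification in
# the high-homology gene: if the HH1 *002 group is present its
# *0020101 sequence joins the alignment reference; if the *0010102
# five-digit variant is present it joins; if both fire, only the
# dominant (*0020101) is added.
design_family_probes <- function(fam) {
  empty <- data.frame(name = character(), target = character(),
                      sequence = character(), threshold = integer(),
                      action = character(), action_arg = character(),
                      precedence_group = character(),
                      precedence = integer(), stringsAsFactors = FALSE)
  if (!any(grepl("^HH1\\*002", fam$prepared$alleles$allele))) {
    return(empty)
  }
  p1 <- design_probe(fam$prepared,
                     grep("^HH1\\*002", fam$prepared$alleles$allele,
                          value = TRUE))
  p2 <- design_probe(fam$prepared,
                     grep("^HH1\\*00102", fam$prepared$alleles$allele,
                          value = TRUE))
  probes <- data.frame(
    name = c("HH1_g002", "HH1_v00102"),
    target = c("HH1*002", "HH1*00102"),
    sequence = c(p1, p2),
    threshold = 10L,
    action = "add_reference_allele",
    action_arg = c("HH1*0020101", "HH1*0010102"),
    precedence_group = "HH1_rules",
    precedence = c(1L, 2L),
    stringsAsFactors = FALSE)
  probes[!is.na(probes$sequence), , drop = FALSE]
}

#' Sample one truth genotype from the haplotype templates
#'
#' Draws two templates with replacement, sums their gene content into
#' per-gene copy numbers, draws that many distinct alleles per gene, and
#' patches any remaining uncharacterized stretches in the drawn
#' (imputed, extended) allele sequences with sequence from a random fully
#' characterized allele of the same gene, so that simulated reads carry
#' no `N`.
#'
#' @param family a `SyntheticFamily`.
#' @param sample_id sample label.
#' @return a `TruthRecord`: list with `sample_id`, `haplotypes`, `copies`
#'   (named integer vector over all genes), `alleles` (per-gene character
#'   vectors) and `seqs` (patched sequences named by allele).
#' @export
sample_genotype <- function(family, sample_id) {
  tpl <- family$templates
  hap <- sample(names(tpl), 2L, replace = TRUE)
  genes <- unique(family$db$alleles$gene)
  copies <- setNames(integer(length(genes)), genes)
  for (h in hap) {
    copies[names(tpl[[h]])] <- copies[names(tpl[[h]])] + tpl[[h]]
  }
  al <- family$prepared$alleles
  picked <- list()
  seqs <- character()
  for (g in genes[copies > 0L]) {
    pool <- al$allele[al$gene == g]
    if (copies[[g]] > length(pool)) {
      stop("gene ", g, ": copy demand ", copies[[g]],
           " exceeds allele pool (", length(pool), ")")
    }
    draw <- sample(pool, copies[[g]], replace = FALSE)
    picked[[g]] <- draw
    for (a in draw) {
      s <- al$seq[al$allele == a]
      if (grepl("N", s, fixed = TRUE)) {
        full <- al$allele[al$gene == g &
                          !grepl("N", al$seq, fixed = TRUE)]
        stopifnot(length(full) > 0L)
        donor_seq <- al$seq[al$allele == sample(full, 1L)]
        npos <- which(seq_chars(s)[[1]] == "N")
        s <- sub_positions(s, npos, bases_at(donor_seq, npos))
      }
      seqs[a] <- s
    }
  }
  structure(list(sample_id = sample_id, haplotypes = hap,
                 copies = copies, alleles = picked, seqs = seqs),
            class = "TruthRecord")
}

#' Simulate paired-end reads for one truth genotype
#'
#' Uniform fragment placement per allele copy at the configured coverage;
#' fragment lengths normal around the configured median; per-base
#' substitution errors follow a logistic ramp along the read from the
#' low to the high configured rate; read names encode sample, source
#' allele and fragment index (`sample|allele|fragment`).
#'
#' @param truth a `TruthRecord`.
#' @param config family configuration (read length, coverage, fragment
#'   and error parameters).
#' @return list with named character vectors `r1` and `r2`.
#' @export
simulate_reads <- function(truth, config) {
  rl <- config$read_len
  r1 <- r2 <- nm <- character()
  for (a in names(truth$seqs)) {
    s <- truth$seqs[[a]]
    len <- nchar(s)
    nfrag <- round(len * config$coverage / (2 * rl))
    if (nfrag <= 0L) next
    frag <- pmin(pmax(round(rnorm(nfrag, config$frag_median,
                                  config$frag_sd)), rl), len)
    start <- floor(runif(nfrag) * (len - frag + 1)) + 1L
    end <- start + frag - 1L
    a1 <- substring(s, start, start + rl - 1L)
    a2 <- revcomp(substring(s, end - rl + 1L, end))
    flip <- runif(nfrag) < 0.5 # fragment sampled from the minus strand
    tmp <- a1[flip]
    a1[flip] <- a2[flip]
    a2[flip] <- tmp
    r1 <- c(r1, a1)
    r2 <- c(r2, a2)
    nm <- c(nm, paste(truth$sample_id, a, seq_len(nfrag), sep = "|"))
  }
  # substitution errors with logistic position ramp
  p <- config$error_rate[1] + diff(config$error_rate) /
    (1 + exp(-(seq_len(rl) - rl / 2) / (rl / 10)))
  lam <- sum(p)
  add_errors <- function(reads) {
    nerr <- rpois(length(reads), lam)
    idx <- rep(which(nerr > 0L), nerr[nerr > 0L])
    if (!length(idx)) return(reads)
    pos <- sample.int(rl, length(idx), replace = TRUE, prob = p)
    cur <- stringi::stri_sub(reads[idx], from = pos, to = pos)
    bases <- c("A", "C", "G", "T")
    new <- bases[(match(cur, bases) - 1L +
                  sample(3L, length(idx), replace = TRUE)) %% 4L + 1L]
    for (k in seq_along(idx)) {
      stringi::stri_sub(reads[idx[k]], from = pos[k], to = pos[k]) <-
        new[k]
    }
    reads
  }
  r1 <- add_errors(r1)
  r2 <- add_errors(r2)
  list(r1 = setNames(r1, paste0(nm, "/1")),
       r2 = setNames(r2, paste0(nm, "/2")))
}

#' Parse truth information out of simulated read names
#'
#' @param read_names character vector of names `sample|allele|fragment`
#'   with an optional `/1` / `/2` mate suffix.
#' @return data.frame with columns `sample_id`, `allele`, `gene`,
#'   `fragment`; rows with unparseable names carry `NA`.
#' @export
parse_read_names <- function(read_names) {
  base <- sub("/[12]$", "", read_names)
  parts <- stringi::stri_split_fixed(base, "|")
  ok <- lengths(parts) == 3L
  out <- data.frame(
    sample_id = ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_),
    allele = ifelse(ok, vapply(parts, `[`, "", 2L), NA_character_),
    fragment = ifelse(ok, vapply(parts, `[`, "", 3L), NA_character_),
    stringsAsFactors = FALSE)
  out$gene <- sub("\\*.*$", "", out$allele)
  out
}

#' Simulate a truth-labeled cohort
#'
#' Draws `n` genotypes from the family templates and writes gzipped
#' paired FASTQ per sample plus a truth table.  All randomness derives
#' from `seed`.
#'
#' @param family a `SyntheticFamily`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param dir output directory.
#' @return list with `manifest` (data.frame: sample_id, fq1, fq2),
#'   `truth` (list of `TruthRecord`s) and `copies` (samples x genes
#'   truth copy matrix).
#' @export
simulate_cohort <- function(family, n, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  truth <- vector("list", n)
  names(truth) <- ids
  manifest <- data.frame(sample_id = ids,
                         fq1 = file.path(dir, paste0(ids, "_1.fastq.gz")),
                         fq2 = file.path(dir, paste0(ids, "_2.fastq.gz")),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- sample_genotype(family, ids[i])
    rd <- simulate_reads(tr, family$config)
    write_fastq(rd$r1, manifest$fq1[i])
    write_fastq(rd$r2, manifest$fq2[i])
    truth[[i]] <- tr
  }
  copies <- do.call(rbind, lapply(truth, `[[`, "copies"))
  rownames(copies) <- ids
  list(manifest = manifest, truth = truth, copies = copies)
}

#' Measured pairwise gene identity of a family
#'
#' Alignment-free per-position identity between the gene reference
#' sequences (first allele of each gene), for checking that realized
#' identities hit the configured bands.
#'
#' @param family a `SyntheticFamily`.
#' @return symmetric matrix of identities in `[0, 1]`.
#' @export
family_identity <- function(family) {
  genes <- unique(family$db$alleles$gene)
  refs <- vapply(genes, function(g) {
    family$db$alleles$seq[family$db$alleles$gene == g][1L]
  }, character(1))
  n <- length(genes)
  out <- matrix(1, n, n, dimnames = list(genes, genes))
  len <- nchar(refs[[1L]])
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      mm <- cpp_pair_mismatch(refs[[i]], refs[[j]])
      out[i, j] <- out[j, i] <- 1 - mm / len
    }
  }
  out
}
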