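---
title: "Genotyping highly homologous gene families with paratype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping highly homologous gene families with paratype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratype)
```

## The problem

Gene families such as the killer-cell immunoglobulin-like receptor (KIR)
complex combine three properties that defeat conventional short-read
pipelines: members share 50--95% of their sequence (so 150 bp reads
frequently align equally well to several genes), individual genes are
present in variable copy number (0--4 per diploid genome, through
haplotypes that delete or duplicate genes), and each gene is highly
polymorphic, with many named alleles that are only partially
characterized in the reference databases (often exons only).
Reads placed on the wrong paralog produce SNP calls that look perfectly
plausible, so errors are silent.  `paratype` implements a genotyping
strategy built around two ideas: determine per-gene *copy number* first
from reads that align *uniquely* to one gene, and then genotype with
alignment references that are dynamically matched to each sample's gene
content and current best genotype, so that reference sequence bias is
progressively removed.

## Database preprocessing

The allele database consists of per-gene allele sequences, per-gene
multiple sequence alignments (MSAs), and feature annotations
(5'UTR/exons/introns/3'UTR).  Three preprocessing steps make partially
characterized alleles usable as alignment references:

* **Imputation** (`impute_database()`): for every uncharacterized
  position of an allele, if all alleles characterized at that MSA
  column agree, the allele receives the consensus base; columns that
  are variable among characterized alleles stay `N`.  "Invariant" is
  defined *among the rows characterized at that column*; a column
  characterized in no row stays `N` and is reported.  Imputed positions
  are flagged separately from natively characterized ones, because the
  two genotyping stages treat them differently (below).
* **UTR extension** (`extend_utrs()`): database alleles typically carry
  only ~250 bp of 5'UTR and ~500 bp of 3'UTR, which depresses alignment
  depth over the first and last exons.  A single donor sequence per
  gene and major allelic group supplies the outer sequence to extend
  both UTRs to 1000 bp.  When no explicit donor is available, the
  longest fully characterized allele of the group is the designated
  donor source.
* **Minimized reference** (`select_minimized_reference()`): aligning
  against every described allele is accurate but costly.  A reference
  of five alleles per gene/major group preserves most of the benefit.
  Selection is deterministic: forced "sequestration" alleles first
  (alleles known to attract off-gene reads), then the most complete
  allele, then greedy max--min Hamming distance among nearly complete
  candidates, with lexicographic tie-breaks.  The greedy rule carries
  the classic factor-2 dispersion guarantee, which the test suite
  checks against exhaustive search on small groups.

Coordinates are 0-based half-open internally and 1-based closed in all
files and reports.

## Copy number from unique-read ratios

For each sample, reads are aligned *exhaustively* (every placement
within the mismatch cap is recorded) against the reference set.  A read
is *unique* to a gene when all its placements fall on alleles of that
gene.  Copy number is batch-calibrated: the per-sample ratio of unique
reads for gene *g* to unique reads for the framework gene (assumed two
copies in every individual) clusters by copy number across a batch.

Automatic thresholding (`auto_thresholds()`) exploits the integer
structure of copy number directly: a gene's batch ratios sit near
`s · copy` for an unknown per-copy spacing `s`, which is fitted by grid
search over candidate spacings derived from the observed ratios.  Each
candidate is scored by the spacing-normalized squared residual of its
implied integer assignment — normalization is what keeps the fit from
drifting toward half-spacings, which always shrink absolute residuals —
with ties broken toward the larger spacing and a final least-squares
refinement.  Cut points sit at half-copy multiples of the fitted
spacing, so a ratio below `s/2` is copy 0.  The spacing is estimated
from the data rather than fixed at the framework-relative 0.5 because
genes whose unique sequence is a small fraction of their length —
pseudogenes that share most of their k-mers with neighbors — have
per-copy spacings far below 0.5.  When the batch realizes only a single
positive copy level the fit is degenerate (`s` and `s/2` explain the
data equally well); the framework-relative 0.5 is then assumed and the
gene flagged.  Genes whose ratios sit near copy boundaries are
likewise *flagged*, and two escape hatches exist:
manual thresholds, and a complementary-pair rule
(`paired_gene_fallback()`: `copy[A] = total − copy[B]`) for allelic
group pairs occupying one locus, applied when the partner separates
cleanly.  Known limitation: if a batch contains only even copies of a
gene with reduced unique fraction (no copy-1 cluster), the spacing
estimate halves and all calls double; the flag marks such genes for
review.

## Genotype determination

Aligned reads are projected onto a per-group coordinate frame
(−1000 bp 5'UTR through +1000 bp 3'UTR, via the MSA columns) and
accumulated into depth tables with independent counts for A, C, G, T,
deletions and insertions.  SNP tables keep positions whose total depth
passes the stage floor (8 initial / 20 final); at each position every
variant with depth ≥ 0.25 of the top variant is recorded, at most
three.

Scoring is mismatch counting.  Homozygous positions score each allele
(mismatch = 1); alleles within a buffer of the best (4 initial / 1
final) are retained.  All allele multisets of size equal to the called
copy number (capped at 3; higher copies are scored at 3 with a warning)
are then enumerated; at heterozygous positions a combination is charged
the symmetric-difference cardinality between the called variant set and
the set of variants the combination offers.  The stages differ
deliberately:

* **initial**: imputed and extended sequences, all
  allele-differentiating positions, uncharacterized comparison bases
  count as full mismatches;
* **final**: unimputed sequences, exonic positions only,
  uncharacterized bases count as matches, and only perfect (score 0)
  combinations are accepted — any mismatch yields an *unresolved*
  genotype rather than a forced call.

A unique best combination is a 7-digit (non-coding resolution) call;
tied combinations that collapse to a single 5-digit multiset resolve at
5 digits; otherwise the call is ambiguous and all alternatives carry
into the next round's reference.  An uncharacterized member of a
combination may stand in for at most one called variant under the
"match" policy, and contributes one guaranteed mismatch under the
"mismatch" policy.

## The genotype-matched alignment workflow

Per sample: (1) exhaustive alignment to a gene-content-matched
reference drawn from the minimized set (genes at copy 0 excluded, the
framework gene always present), unique reads only, initial genotype;
(2) two genotype-matched exhaustive rounds in which the reference is
the current typing (including ambiguity); (3) a final non-exhaustive
round against the locked and most congruent typings, processing *all*
aligned reads (by then the reference contains few wrong attractors, and
unique-only filtering would discard informative reads).  Congruence is
the least SNP mismatch score across rounds, compared at 7-digit
resolution with lexicographic tie-breaks.

Three countermeasures prevent the loop from locking in its own
mistakes:

* perfect, unambiguous typings are **locked** and never recomputed in
  later intermediate rounds;
* any gene whose typing mismatches its aligned SNPs receives the five
  diverse minimized alleles in the next reference (**anti-stuck**) —
  a mismatching typing indicates misaligned reads that will otherwise
  recur under the same reference;
* genes represented only by partially characterized sequence receive
  their most complete minimized allele, since `N` stretches in a
  reference attract spurious placements.

Virtual probes (exact substring counts over the raw reads, both
strands, distinct read sequences only, hit threshold 10) drive
table-based reference refinement rules with precedence groups: when
several alleles of a problematic group fire at once, only the dominant
rule's allele is added.  Probe tables are data (TSV), not code.

Output formatting adds `null` alleles for genes at copy 0 or 1, merges
configured allelic-group pairs into single columns, and renders
ambiguity as a sorted `|`-separated list.

## The built-in aligner

The aligner indexes every reference k-mer and seeds each read with
`max_mm + 1` disjoint segments, so by the pigeonhole principle every
ungapped placement within the mismatch cap (default 6 per 150 bp) is
recovered; verification is exact mismatch counting with reference `N`
matching any base at zero penalty.  The test suite checks equivalence
against a full sliding-window scan.  Verification is ungapped by
design: the packaged simulator's error model is substitution-only and
synthetic families carry no structural indels, so gapped alignment
would add cost without exercising any additional code path; for
production data from external aligners, a SAM adapter
(`read_sam()`/`write_sam()`) accepts ungapped records from any source.
Seeds containing `N` are skipped, so the completeness guarantee applies
across fully characterized reference windows; the extraction stage uses
a looser cap (10) because filtration is recall-critical.

## The synthetic family

`family_config()`/`build_family()` define the packaged study
conditions.  Eleven genes derive from a common ancestor with
divergences chosen so pairwise identities span the 50--95% homology
range observed in real families: a distinct framework gene (`FW1`), a
distinct presence/absence gene (`PA1`), a fully characterized
distinct-sequence gene (`DS1`, the analog of a gene like KIR2DL4 whose
sequence is largely private), a high-homology pair (`HH1`/`HH2`, 97%
identity — the KIR2DL1/KIR2DS1 regime; one `HH2` allele group carries a
250 bp gene-conversion block from `GL1`, the kind of sequestration-prone
allele whose reads misalign wholesale under single-sequence-per-gene
references), two allelic-group pairs
(`GL1`/`GL2`, complementary on every haplotype; `GS1`/`GS2`), a gene
with half its alleles characterized only across exons (`XA1`), and a
pseudogene analog (`PS1`) assembled as a mosaic of exact `HH1` and
`GS1` blocks around a 150 bp private segment, so that it shares >80% of
its 150-mers with its neighbors while retaining a small unique region —
the regime in which copy calling must rely on a compressed unique-read
signal.

Allele series encode the digit-resolution semantics: 3-digit groups
differ at several exonic positions, 5-digit variants at further exonic
positions, 7-digit variants only at non-coding positions.  Eight
haplotype templates provide gene absence and one duplication; two
templates drawn with replacement define each sample's copy numbers, and
alleles are drawn without replacement per gene.  Uncharacterized
stretches in drawn alleles are patched from a random fully
characterized allele of the same gene before read generation, so reads
never contain `N` (mirroring how partially characterized alleles occur
inside real, fully sequenced genomes).

Reads are 150 bp paired-end at 50x coverage with fragment lengths
normal around a median of 200 (sd 30, a conventional tight library).
Substitution errors follow a logistic ramp along the read from 0.2% to
0.6%, emulating the rising error of sequencing-by-synthesis chemistry
without shipping any instrument's empirical quality profiles; indel
errors are off by default.  Read names encode sample, source allele and
fragment, so every misaligned read can be traced (`trace_flows()`).

What the simulator does *not* emulate — and what passing tests
therefore do not show about real data: intergenic sequence (reads from
flanking regions that can cross-map into genes), novel alleles absent
from the database, quality-score-correlated errors, indels, and batch
effects between sequencing runs.  Cohort-scale validation on real data
remains the standard for those factors.

## Problem sizes and numerical choices

The packaged acceptance analyses use a 50-sample cohort of the
eleven-gene family at 50x coverage (alleles ~2.9 kb after extension),
sizes at which the full pipeline — simulation, extraction, two copy
determinations and the four-round genotyping workflow — completes on a
single CPU in well under the analysis-session times a desk check
allows, while still realizing every copy state (0/1/2, plus one
duplication) and every designed homology regime.  Determinism: a single
integer seed fixes family structure (a packaged constant) and, per run,
cohort sampling and read simulation; alignment, copy calling and
genotyping are deterministic given their inputs, with documented
lexicographic tie-breaks.  Boundary conventions: a ratio equal to a
copy threshold takes the higher copy; depth positions below the stage
floor are dropped, not interpolated; reads equal-scoring on several
references in the final (best-placement) round take the
lexicographically first reference.

## Known limitations

Copy calling for genes whose unique fraction varies strongly with the
allele drawn (the `HH2` regime: which allele a sample carries changes
how many of its reads are unique) can produce overlapping ratio
clusters; such genes are flagged rather than silently called, matching
the behavior of batch-calibrated copy callers on the hardest paralog
pairs.  Intermediate genotyping rounds filter to unique reads, so a
gene whose every read cross-maps (complete containment in a homolog)
cannot be genotyped from unique evidence and reports `no_reads`.  The
ungapped aligner does not place reads across indel polymorphisms;
families with common indel alleles require an external gapped aligner
through the SAM adapter.
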