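---
title: "Models and conventions behind guidescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind guidescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidescreen)
```

guidescreen implements the dry-lab side of a Cas9 guide-RNA knockout
campaign against a gene with two coding isoforms sharing their 3' CDS:
guide enumeration and annotation, off-target profiling, amplicon-based
editing quantification, and transcriptional-response scoring. This
vignette records the models, conventions and numerical choices in enough
detail that every reported number can be re-derived.

## Coordinates and the gene model

All internal arithmetic uses 0-based half-open intervals; every
user-visible index (CDS nucleotide, codon, exon, table output) is
1-based. A `gene_model` holds one gene's merged exon chain plus per-
isoform CDS intervals. When two or more isoforms are present the shorter
must be a frame-preserving 5'-truncation of the longest: its spliced CDS
is required, at construction time, to be a byte-identical suffix of the
long isoform's spliced CDS. This is the structure that makes
"long-isoform-only" targeting meaningful — a cut in the long isoform's
unique 5' region leaves the short protein intact, while a cut in the
shared 3' CDS disrupts both.

`project_genomic_to_cds()` maps a genomic position to its 1-based
position along the spliced CDS read 5'→3' on the coding strand and is
exactly inverted by `cds_to_genomic()`; both are exercised as a
bijection over every CDS position in the tests.

## Cut-site and codon indexing

The SpCas9 blunt cut is placed between protospacer positions 17 and 18,
three nucleotides 5' of the PAM. Two conventions follow:

* `cut_site` reports the genomic position of protospacer position 17 —
  the nucleotide 5' of the cut *on the protospacer strand*.
* The CDS index of a cut is taken from the nucleotide 5' of the cut
  junction *in coding-strand orientation*. For guides antisense to the
  coding strand these differ by one base; resolving "the nucleotide to
  the left of the cut" in CDS orientation keeps the codon assignment
  strand-consistent. This is a documented reconciliation of two common
  phrasings (left of the cut vs. 4 bp from the PAM), not a universal
  standard.

The codon index is `ceiling(cds_index / 3)`: a cut falling between two
codons indexes the N-terminal codon. The design filter's "cut sites
before codon `max_codon`" is strict (`codon <= max_codon - 1`); because
the boundary reading is genuinely ambiguous, guides landing on codons
`max_codon - 1` or `max_codon` carry a `boundary_codon` flag so either
convention can be audited.

## Near-cognate start-codon risk

Guides cutting very close to the 5' start can leave a downstream
in-frame CUG able to re-initiate translation with near-cognate
efficiency, producing an N-terminally trimmed but functional protein.
`scan_inframe_near_cognate()` reports in-frame CTG positions within a 5'
search window (default 450 nt = 150 codons — the window is not pinned
down by any published convention, so it is a tunable with a deliberate,
conservative default), and any guide whose cut CDS index lies 5' of such
a codon is flagged `upstream_of_inframe_cug`. Candidate selection can
then exclude those guides, mirroring the empirical observation that they
edit without ablating protein.

## Off-target model and specificity scores

The scanner reports every 23-nt window, on either strand, whose last
three bases match the PAM pattern (default NRG) and whose first 20 bases
are within `max_mismatches` Hamming distance of the spacer. PAM bases
are never counted as mismatches; windows containing `N` never match;
bulged (gapped) sites are out of scope by design and requesting them is
an error. The implementation is a vectorized shift-and-compare over the
contig and is verified, exhaustively for mismatch tolerances 0–4,
against a naive per-window oracle written independently in the tests.

"Likely specific" means no site other than the intended locus at fewer
than 3 mismatches. Species reactivity means a perfect 20-mer match with
an NGG PAM anywhere in the comparator genome.

Two per-hit scores are provided:

* **CFD** — the product over mismatched positions of per-(position,
  guide base, site base) activity fractions times a PAM-dinucleotide
  penalty; a perfect NGG site scores exactly 1. The tables shipped under
  `inst/extdata/` are clearly labelled *synthetic* stand-ins with the
  real schema (penalties decline toward the PAM, transversions penalized
  more); any empirically derived table with the same columns can be
  passed instead.
* **MIT** — per hit with `m` mismatches at positions `p`,
  `100 · Π(1−w[p]) · 1/(((19−d̄)/19)·4+1) · 1/m²`, with `d̄` the mean
  pairwise distance between mismatch positions (`d̄ = 19` when `m ≤ 1`,
  making the spacing term 1). The shipped position weights are the
  published 20-element vector. The aggregate guide score is
  `100 · 100/(100 + Σ per-hit)` over off-target hits: 100 with no
  off-targets and strictly decreasing as hits accumulate. The CFD
  aggregate is defined analogously (`100·cfd` per hit) as this package's
  convention.

Context classification is by 1-nt interval overlap: exonic beats
intronic beats intergenic. The paralog check simply restricts a relaxed
scan (≤ 4 mismatches) to supplied paralog CDS intervals.

## Amplicon quantification

Reads are globally aligned to the amplicon (match +2, mismatch −1, gap
open 6, gap extend 1 — CRISPResso-like scoring, configurable), trying
both orientations and keeping the higher score. Identity is matches over
aligned columns, gap columns included; reads under the homology floor
(default 70%) are discarded and excluded from every denominator.

The quantification window of width `w` sits at offset −3 from the
PAM-proximal protospacer end: `ceiling(w/2)` positions left of the cut
junction and `floor(w/2)` right of it, in amplicon coordinates. With the
default `w = 1` it is the single base 5' of the blunt cut. Deletions
occupy amplicon intervals; insertions are assigned to the junction
position left of the inserted bases.

One subtlety matters in practice: gap placement inside a repeat is
ambiguous, and the aligner's choice is arbitrary (Biostrings
right-aligns). A one-base insertion exactly at the cut can therefore be
reported one or more bases away whenever the inserted base extends a
homopolymer. An indel is consequently counted as window-overlapping if
*any* of its equivalent placements — the left-shifted through
right-shifted range within its homology run — overlaps the window. This
makes calls independent of aligner tie-breaking and of read strand.

A read is `modified` iff at least one indel overlaps the window;
substitutions alone never modify. The net indel length per read (sum of
signed window-overlapping indel lengths) determines frame status:
`frameshift` iff `net %% 3 != 0`. Rates are computed over non-discarded
reads, and zero usable reads yield an explicit no-data result rather
than 0. Replicate summaries report mean ± sample SD with a deterministic
rank (descending mean frameshift, ties by spacer lexicographic order).

The deviation flag for in-frame-skewed repair uses a two-sided exact
binomial test of the frameshift count among modified reads against 2/3 —
the fraction expected if net lengths were uniform mod 3 — flagging when
p < 0.05 with the observed fraction below 2/3. This test is this
package's explicit stand-in for an unstated convention; its behaviour at
small n follows the exact test (5 of 10 does not flag; 1000 of 2000
does).

## Transcriptional response

The count pipeline is deliberately simple and fully specified:

* genes with mean count < 10 across samples are removed (boundary
  inclusive at 10);
* size factors are median-of-ratios (genes with any zero excluded from
  the median), normalized to geometric mean 1 — cross-checked in the
  tests against DESeq2's reference implementation up to overall scale;
* the stabilizing transform is `log2(count/factor + 1)`, a documented
  simplification of the blind variance-stabilizing transform (it is
  monotone, maps 0 to 0, and compresses the ISG module's variance by
  orders of magnitude on simulated data);
* PCA takes the 500 most variable transformed genes, centers rows, and
  uses SVD; PC1's sign (arbitrary under SVD) is oriented so editing
  samples score at least as high as negative controls, making plots and
  regressions deterministic;
* differential expression uses the group-mean log2 fold change with a
  0.5 pseudocount, a two-sided Welch t test on `log2(normalized + 0.5)`
  replicate values, Benjamini–Hochberg adjustment, and the flag
  `|log2FC| >= 0.58 & padj < 0.05 & base_mean >= 3`. The threshold
  semantics, not the inferential engine, are the point: the engine is a
  transparent replacement for a shrunken negative-binomial Wald test,
  and the fold-change threshold is read as absolute value (the
  directional phrasing it descends from is internally inconsistent with
  induced gene lists), with the direction reported alongside.

Response regressions are ordinary least squares of a per-sample response
(PC1 or a gene's expression) on the frameshift rate, with optional guide
exclusions (e.g. the upstream-of-CUG guides, which edit without protein
loss and would otherwise dilute the relationship).

## What the synthetic data emulate

`sim_gene_fixture()` builds a 20-kb contig carrying a 9-exon gene: long
CDS of 1200 codons starting ATG and ending TAA, exactly one in-frame CTG
in the 5' search window (planted at codon 40, others scrubbed), and a
short isoform starting at codon 250 whose CDS is a suffix of the long
one. `plant_site()` writes spacer copies with controlled mismatch counts
for off-target and species-homology truths. `sim_reads()` draws each
read i.i.d. from a programmed net-indel spectrum, placing deletions
immediately 5' of the cut and insertions (random bases, drawn per read)
at the junction, adds uniform substitution errors (default 0.001/base,
a post-filter Illumina-like rate) and emits each read on a random
strand. `sim_counts()` draws gene baselines log-normally
(meanlog log 100, sdlog 1) and counts as negative binomial with mean
`mu_g · 2^(slope · frameshift_s · induction_g)`; the 50-gene ISG module
gets induction weights in [0.5, 1] × 4 with CXCL10 at the maximum, and
null genes 0. Guide-level frameshift rates span 0.1–0.8 with 3
replicates per arm and small replicate jitter.

The dispersion default (0.02) deserves a note. With 3 replicates per
arm, a gene-wise Welch test's degrees of freedom lie in [2, 4], which
caps how small a p-value even an enormous fold change can attain; after
BH adjustment across ~2000 genes, ISG-module sensitivity of at least 90%
is only reachable when dispersion is at or below roughly 0.02. That
noise level is consistent with parallel nucleofections of a single donor
preparation (technical-scale variability); true multi-donor biological
replication would be several-fold noisier, and sensitivity then drops to
roughly 60–80% — not because the effect vanishes but because of the
Welch df floor. This is precisely the regime where shared-dispersion NB
engines (DESeq2, edgeR) outperform gene-wise tests, and it is a known
limitation of the simplified engine here.

What the generators do **not** emulate: sequence-context-dependent
repair spectra (microhomology bias), PCR duplicates and quality decay,
multi-locus amplicons, batch structure in counts, and correlated ISG
co-regulation beyond a shared induction driver. Passing tests therefore
demonstrate correctness of the arithmetic and estimators under clean
generative assumptions, not robustness to every artifact of real
libraries.

## Problem sizes and determinism

The default desk scale — 20-kb contig, ~1100–1300 candidate
protospacers, 10,000 reads for recovery checks, 22-guide screens at 800
reads × 3 replicates, 2000-gene count matrices with 33 samples — was
chosen so the entire test suite and the acceptance script each run in
minutes on one core while keeping binomial/regression standard errors
small relative to the tolerances asserted. Every generator takes an
explicit seed and is byte-reproducible; the acceptance script derives
all sub-seeds from its single `--seed` argument.

## Known limitations

* No bulged off-target search, by design; empirically nominated
  off-target sites are out of scope.
* The shipped CFD tables are synthetic stand-ins; absolute CFD values
  are only meaningful relative to the table supplied.
* On-target efficiency prediction is not computed; an externally
  supplied score column can ride along through the tibble interfaces.
* The DE engine's small-sample power ceiling, discussed above.
* GFF3 support is deliberately minimal (one gene; gene/mRNA/exon/CDS
  features only).
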