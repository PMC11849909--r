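# Seeded synthetic-data generators: a toy genome with a two-isoform gene,
# planted off-target copies, amplicon reads with programmed indel spectra,
# and negative-binomial count matrices carrying an interferon-stimulated
# gene module whose induction scales with editing rate. Every generator
# takes an explicit seed and is byte-reproducible.

#' Simulate a toy genome containing a two-isoform gene
#'
#' Builds a random contig carrying one gene whose long-isoform CDS starts
#' with ATG, ends with a stop codon, and contains exactly one in-frame CTG
#' in the 5' search window, planted at `cug_codon`. The short isoform is a
#' frame-preserving 5'-truncation starting at `short_start_codon`, so its
#' spliced CDS is a suffix of the long isoform's — the p150/p110
#' structure where the short protein is entirely encoded within the long
#' one.
#'
#' @param seed Integer seed.
#' @param contig_len Contig length in nt (default 20000).
#' @param n_exons Number of exons (default 9).
#' @param cds_codons Long-isoform CDS length in codons, stop included
#'   (default 1200).
#' @param utr5,utr3 UTR lengths inside the first/last exon (default 60).
#' @param cug_codon Codon index of the planted in-frame CTG (default 40).
#' @param cug_window_nt Window within which all other in-frame CTGs are
#'   scrubbed (default 450).
#' @param short_start_codon First codon of the short isoform (default 250;
#'   must be downstream of `cug_codon`).
#' @param strand Gene strand (default `"+"`; `"-"` mirrors the fixture).
#' @return List: `genome` (named character vector), `model` (a
#'   `gene_model` with isoforms `long` and `short`), and `truth` (list with
#'   `cug_codon`, `cug_cds_nt`, `short_start_codon`, `cds`).
#' @export
sim_gene_fixture <- function(seed = 1L, contig_len = 20000L, n_exons = 9L,
                             cds_codons = 1200L, utr5 = 60L, utr3 = 60L,
                             cug_codon = 40L, cug_window_nt = 450L,
                             short_start_codon = 250L, strand = "+") {
  stopifnot(short_start_codon > cug_codon, (short_start_codon - 1L) %% 1L == 0)
  set.seed(seed)
  cds_len <- 3L * cds_codons

  # spliced CDS: ATG ... planted CTG at cug_codon ... stop; scrub other
  # in-frame CTGs inside the search window so the truth is exact
  codons_pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                   c("A","C","G","T")), 1, paste, collapse = "")
  codons_pool <- setdiff(codons_pool, c("TAA", "TAG", "TGA"))
  cds_codon_vec <- sample(codons_pool, cds_codons, replace = TRUE)
  cds_codon_vec[1] <- "ATG"
  cds_codon_vec[cds_codons] <- "TAA"
  window_codons <- seq_len(min(ceiling(cug_window_nt / 3), cds_codons))
  scrub <- window_codons[cds_codon_vec[window_codons] == "CTG"]
  cds_codon_vec[scrub] <- "CTT"
  cds_codon_vec[cug_codon] <- "CTG"
  cds <- paste(cds_codon_vec, collapse = "")

  # exon layout: split the transcript (utr5 + CDS + utr3) into n_exons
  tx_len <- utr5 + cds_len + utr3
  cuts <- sort(sample(seq(200L, tx_len - 200L, by = 50L), n_exons - 1L))
  exon_lens <- diff(c(0L, cuts, tx_len))
  intron_lens <- sample(200:1500, n_exons - 1L, replace = TRUE)
  gene_len <- sum(exon_lens) + sum(intron_lens)
  if (gene_len + 400L > contig_len) {
    rlang::abort("infeasible layout: gene does not fit the contig",
                 class = "guidescreen_parameter_error")
  }
  gene_start <- sample(200:(contig_len - gene_len - 200L), 1L)
  ex_starts <- gene_start + cumsum(c(0L, utils::head(exon_lens, -1) +
                                       intron_lens))
  exons <- tibble::tibble(start = as.integer(ex_starts),
                          end = as.integer(ex_starts + exon_lens))

  # map transcript coordinates (0-based) to genomic (plus strand so far)
  tx2g <- unlist(lapply(seq_len(n_exons), function(i)
    seq(exons$start[i], exons$end[i] - 1L)))
  cds_tx <- seq(utr5, utr5 + cds_len - 1L)          # 0-based transcript coords
  cds_g <- tx2g[cds_tx + 1L]

  contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
  chars <- .seq_chars(contig)
  chars[cds_g + 1L] <- .seq_chars(cds)
  contig <- paste(chars, collapse = "")

  long_iv <- .positions_to_intervals(cds_g)
  short_g <- cds_g[seq(3L * (short_start_codon - 1L) + 1L, cds_len)]
  short_iv <- .positions_to_intervals(short_g)

  if (strand == "-") {
    mirror <- function(iv) tibble::tibble(start = contig_len - iv$end,
                                          end = contig_len - iv$start)[nrow(iv):1, ]
    contig <- revcomp(contig)
    exons <- mirror(exons); long_iv <- mirror(long_iv); short_iv <- mirror(short_iv)
  }
  genome <- c(toy_chr = contig)
  model <- gene_model("toygene", "toy_chr", strand, exons,
                      list(long = long_iv, short = short_iv))
  list(genome = genome, model = model,
       truth = list(cug_codon = cug_codon, cug_cds_nt = 3L * (cug_codon - 1L) + 1L,
                    short_start_codon = short_start_codon, cds = cds))
}

.positions_to_intervals <- function(pos0) {
  pos0 <- sort(pos0)
  brk <- c(0L, which(diff(pos0) != 1L), length(pos0))
  tibble::tibble(
    start = pos0[utils::head(brk, -1) + 1L],
    end = pos0[brk[-1]] + 1L
  )
}

#' Plant a copy of a spacer (with controlled mismatches) into a genome
#'
#' Overwrites the 23-nt window starting at `pos` with the spacer plus PAM,
#' after introducing exactly `mismatches` base changes at seeded random
#' spacer positions. Used to create ground-truth off-target sites and
#' cross-species matches.
#'
#' @param genome Named character vector of contigs.
#' @param contig Target contig.
#' @param pos 1-based position for the start of the 23-nt site.
#' @param spacer 20-nt spacer.
#' @param mismatches Number of mismatched spacer positions (default 0).
#' @param pam 3-nt PAM to write (default `"AGG"`).
#' @param strand Strand on which the planted site reads spacer+PAM
#'   (default `"+"`).
#' @param seed Integer seed for the mismatch placement.
#' @return List: `genome` (modified) and `truth` (one-row tibble with the
#'   planted site's coordinates, strand and mismatch count).
#' @export
plant_site <- function(genome, contig, pos, spacer, mismatches = 0L,
                       pam = "AGG", strand = "+", seed = 1L) {
  set.seed(seed)
  spacer <- toupper(spacer)
  stopifnot(nchar(spacer) == 20L, nchar(pam) == 3L)
  sc <- .seq_chars(spacer)
  if (mismatches > 0L) {
    at <- sample(20L, mismatches)
    for (i in at) sc[i] <- sample(setdiff(c("A", "C", "G", "T"), sc[i]), 1L)
  }
  site <- paste0(paste(sc, collapse = ""), pam)
  if (strand == "-") site <- revcomp(site)
  seq <- genome[[contig]]
  stopifnot(pos >= 1L, pos + 22L <= nchar(seq))
  substr(seq, pos, pos + 22L) <- site
  genome[[contig]] <- seq
  list(genome = genome,
       truth = tibble::tibble(contig = contig, start = pos, end = pos + 22L,
                              strand = strand,
                              mismatch_count = as.integer(mismatches)))
}

#' Extract an amplicon around a guide's cut site
#'
#' @param genome Named character vector of contigs.
#' @param guide One-row tibble with `contig`, `cut_site`, `spacer`
#'   (from [enumerate_protospacers()]).
#' @param flank Bases kept on each side of the cut (default 150, giving a
#'   ~300-nt amplicon as in typical amplicon-seq primer designs).
#' @return Amplicon sequence (plus-strand of the reference).
#' @export
guide_amplicon <- function(genome, guide, flank = 150L) {
  seq <- genome[[guide$contig]]
  lo <- max(1L, guide$cut_site - flank)
  hi <- min(nchar(seq), guide$cut_site + flank)
  substr(seq, lo, hi)
}

#' Simulate amplicon reads with a programmed indel spectrum
#'
#' Each read is drawn i.i.d. from the spectrum of net indel lengths
#' (0 = unedited). Insertions add random bases at the cut junction;
#' deletions remove bases immediately 5' of the junction. Uniform
#' substitution errors are applied at `error_rate` per base, and each read
#' is emitted on a random strand. Truth fractions are recorded for
#' recovery tests.
#'
#' @param assay An [amplicon_assay()].
#' @param spectrum Tibble/data frame with `net_indel` (signed integers,
#'   0 = unedited) and `prob` columns; probabilities must sum to 1.
#' @param error_rate Per-base substitution error probability (default
#'   0.001).
#' @param n Number of reads (default 1000).
#' @param seed Integer seed.
#' @return List: `reads` (named character vector) and `truth` (one-row
#'   tibble: `indel_rate`, `frameshift_rate`, the programmed fractions).
#' @export
sim_reads <- function(assay, spectrum, error_rate = 0.001, n = 1000L, seed = 1L) {
  stopifnot(inherits(assay, "amplicon_assay"))
  spectrum <- tibble::as_tibble(spectrum)
  if (abs(sum(spectrum$prob) - 1) > 1e-8) {
    rlang::abort("spectrum probabilities must sum to 1",
                 class = "guidescreen_parameter_error")
  }
  set.seed(seed)
  j <- assay$cut_junction
  amp <- assay$amplicon
  draw <- sample.int(nrow(spectrum), n, replace = TRUE, prob = spectrum$prob)
  net <- spectrum$net_indel[draw]
  reads <- character(n)
  reads[net == 0L] <- amp
  for (d in unique(net[net < 0L])) {
    reads[net == d] <- paste0(substr(amp, 1L, j + d), substr(amp, j + 1L, nchar(amp)))
  }
  for (d in unique(net[net > 0L])) {
    at <- which(net == d)
    inserted <- vapply(at, function(i)
      paste(sample(c("A", "C", "G", "T"), d, replace = TRUE), collapse = ""),
      character(1))
    reads[at] <- paste0(substr(amp, 1L, j), inserted,
                        substr(amp, j + 1L, nchar(amp)))
  }
  # substitution noise
  n_err <- stats::rbinom(n, nchar(reads), error_rate)
  for (i in which(n_err > 0)) {
    ch <- .seq_chars(reads[i])
    at <- sample(length(ch), n_err[i])
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  flip <- stats::runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  names(reads) <- sprintf("read%05d", seq_len(n))
  edited <- spectrum$net_indel[draw] != 0L
  fs <- spectrum$net_indel[draw] %% 3L != 0L
  list(reads = reads,
       truth = tibble::tibble(indel_rate = mean(edited),
                              frameshift_rate = mean(fs),
                              programmed_indel = sum(spectrum$prob[spectrum$net_indel != 0]),
                              programmed_frameshift = sum(spectrum$prob[spectrum$net_indel %% 3 != 0])))
}

#' Build per-sample metadata for a simulated response experiment
#'
#' Guides are assigned frameshift rates evenly spaced over `fs_range` and
#' alternate between long-isoform-specific and dual-isoform targeting;
#' negative controls have rate 0. Replicate-level rates get small seeded
#' jitter, as replicate nucleofections do in practice.
#'
#' @param n_guides Number of target-gene guides (default 8).
#' @param n_controls Number of negative-control guides (default 3).
#' @param n_replicates Replicates per guide (default 3).
#' @param fs_range Range of per-guide frameshift rates (default 0.1-0.8).
#' @param jitter_sd SD of replicate-level jitter (default 0.02).
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `guide_id`, `group`, `frameshift_rate`,
#'   `replicate`.
#' @export
sim_response_meta <- function(n_guides = 8L, n_controls = 3L, n_replicates = 3L,
                              fs_range = c(0.1, 0.8), jitter_sd = 0.02, seed = 1L) {
  set.seed(seed)
  guides <- tibble::tibble(
    guide_id = sprintf("cg%03d", seq_len(n_guides)),
    group = rep(c("adar_targeting_p150", "adar_targeting_dual"),
                length.out = n_guides),
    fs = seq(fs_range[1], fs_range[2], length.out = n_guides)
  )
  ctrls <- tibble::tibble(guide_id = sprintf("ctrl%02d", seq_len(n_controls)),
                          group = "negative_control", fs = 0)
  all <- dplyr::bind_rows(guides, ctrls)
  meta <- tidyr::crossing(all, replicate = seq_len(n_replicates))
  meta$frameshift_rate <- pmax(0, meta$fs +
                                 stats::rnorm(nrow(meta), 0, jitter_sd) * (meta$fs > 0))
  meta$sample_id <- paste0(meta$guide_id, "_r", meta$replicate)
  meta[, c("sample_id", "guide_id", "group", "frameshift_rate", "replicate")]
}

#' Simulate a count matrix with an editing-scaled ISG module
#'
#' Gene baselines are drawn log-normally; counts are negative binomial with
#' mean `mu_g x 2^(slope x frameshift_s x induction_g)` and gene-wise
#' dispersion. Interferon-stimulated-module genes get induction weights in
#' `[0.5, 1] x max_log2_induction`; `CXCL10` is included in the module at
#' the maximum weight; all other genes have induction 0.
#'
#' @param meta Sample metadata from [sim_response_meta()] (needs
#'   `sample_id` and `frameshift_rate`).
#' @param n_genes Total genes (default 2000).
#' @param n_isg Size of the ISG module (default 50).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of gene
#'   baseline means (defaults `log(100)`, 1).
#' @param dispersion NB dispersion (default 0.02, typical of parallel
#'   same-donor replicate treatments; `size = 1/dispersion`).
#' @param max_log2_induction Maximum per-gene log2 induction at 100%
#'   editing (default 4).
#' @param slope Editing-to-induction slope (default 2).
#' @param seed Integer seed.
#' @return List: `counts` (genes x samples integer matrix) and `truth`
#'   (tibble: `gene`, `is_isg`, `induction`).
#' @export
sim_counts <- function(meta, n_genes = 2000L, n_isg = 50L,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.02, max_log2_induction = 4, slope = 2,
                       seed = 1L) {
  stopifnot(n_isg >= 1L, n_isg < n_genes, dispersion > 0)
  set.seed(seed)
  genes <- c("CXCL10",
             if (n_isg > 1) sprintf("ISG%03d", seq_len(n_isg - 1L)),
             sprintf("GENE%04d", seq_len(n_genes - n_isg)))
  induction <- c(max_log2_induction,
                 if (n_isg > 1) stats::runif(n_isg - 1L, 0.5, 1) * max_log2_induction,
                 rep(0, n_genes - n_isg))
  mu0 <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  fs <- meta$frameshift_rate
  counts <- matrix(0L, n_genes, nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    mu <- mu0 * 2^(slope * fs[s] * induction)
    counts[, s] <- stats::rnbinom(n_genes, size = 1 / dispersion, mu = mu)
  }
  list(counts = counts,
       truth = tibble::tibble(gene = genes, is_isg = induction > 0,
                              induction = induction))
}
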