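# Mismatch-tolerant off-target scanning, specificity classification,
# CFD/MIT scoring, genomic-context and paralog checks.

#' Scan a genome for off-target sites of a spacer
#'
#' Reports every 23-nt window, on either strand, whose last three bases
#' match the PAM pattern and whose first 20 bases are within
#' `max_mismatches` Hamming distance of the spacer. PAM positions are never
#' counted as mismatches; windows containing `N` never match. Gapped
#' (bulged) alignment is unsupported by design: both bulge sizes must be 0.
#'
#' @param spacer 20-nt spacer sequence (protospacer strand, 5'->3').
#' @param genome Named character vector of contigs.
#' @param max_mismatches Maximum Hamming distance over the 20 spacer
#'   positions (default 2, i.e. "fewer than 3 mismatches").
#' @param pam IUPAC PAM pattern; default `"NRG"`, the relaxed SpCas9 PAM
#'   used for off-target nomination.
#' @param dna_bulge,rna_bulge Must be 0; any other value is an
#'   unsupported-parameter error.
#' @return Tibble with one row per hit: `contig`, `start`, `end` (1-based
#'   inclusive 23-nt footprint), `strand`, `site_seq` (protospacer-strand
#'   23-mer), `pam_observed`, `mismatch_count`, and `mismatches`, a list
#'   column of tibbles (`position` 1-20, `guide_base`, `site_base`).
#' @export
scan_offtargets <- function(spacer, genome, max_mismatches = 2L, pam = "NRG",
                            dna_bulge = 0L, rna_bulge = 0L) {
  if (dna_bulge != 0L || rna_bulge != 0L) {
    rlang::abort("bulged off-target search is unsupported: dna_bulge and rna_bulge must be 0",
                 class = "guidescreen_parameter_error")
  }
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L || grepl("[^ACGT]", spacer)) {
    rlang::abort("spacer must be a 20-nt ACGT string", class = "guidescreen_parameter_error")
  }
  pam_letters <- .check_iupac(pam)
  spacer_chars <- .seq_chars(spacer)
  rows <- list()
  for (contig in names(genome)) {
    chars <- .seq_chars(genome[[contig]])
    L <- length(chars)
    # plus strand
    st <- .pam_window_starts(chars, pam_letters)
    mm <- .window_mismatches(chars, spacer_chars, st)
    keep <- mm <= max_mismatches
    if (any(keep)) {
      rows[[length(rows) + 1L]] <-
        .hit_rows(genome[[contig]], contig, st[keep], mm[keep], "+", spacer_chars, L)
    }
    # minus strand: scan the reverse complement, map starts back
    rc_chars <- rev(chartr("ACGTN", "TGCAN", chars))
    st_rc <- .pam_window_starts(rc_chars, pam_letters)
    mm_rc <- .window_mismatches(rc_chars, spacer_chars, st_rc)
    keep <- mm_rc <= max_mismatches
    if (any(keep)) {
      rows[[length(rows) + 1L]] <-
        .hit_rows(genome[[contig]], contig, L - (st_rc[keep] + 23L), mm_rc[keep], "-",
                  spacer_chars, L)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else .empty_hits()
  out <- out[order(out$contig, out$start, out$strand), ]
  tibble::as_tibble(out)
}

.empty_hits <- function() {
  tibble::tibble(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), site_seq = character(0),
                 pam_observed = character(0), mismatch_count = integer(0),
                 mismatches = list())
}

.hit_rows <- function(seq, contig, starts0, mm, strand, spacer_chars, L) {
  window <- substring(seq, starts0 + 1L, starts0 + 23L)
  site_seq <- if (strand == "+") window else revcomp(window)
  detail <- lapply(site_seq, function(w) {
    wc <- .seq_chars(substr(w, 1L, 20L))
    p <- which(wc != spacer_chars)
    tibble::tibble(position = p, guide_base = spacer_chars[p], site_base = wc[p])
  })
  tibble::tibble(contig = contig, start = as.integer(starts0 + 1L),
                 end = as.integer(starts0 + 23L), strand = strand,
                 site_seq = site_seq, pam_observed = substr(site_seq, 21L, 23L),
                 mismatch_count = as.integer(mm), mismatches = detail)
}

#' Is a guide likely specific?
#'
#' A guide is classified likely specific when it has no off-target location
#' with fewer than 3 mismatches: every hit at `<= mm_threshold` mismatches
#' must coincide with the intended on-target locus.
#'
#' @param hits Tibble from [scan_offtargets()] run with
#'   `max_mismatches >= mm_threshold`.
#' @param on_target List or one-row data frame with `contig`, `start`,
#'   `strand` of the intended site (1-based start of the 23-nt footprint).
#' @param mm_threshold Mismatch cutoff defining "near" hits (default 2).
#' @return Logical scalar.
#' @export
is_likely_specific <- function(hits, on_target, mm_threshold = 2L) {
  near <- hits[hits$mismatch_count <= mm_threshold, ]
  all(near$contig == on_target$contig &
        near$start == on_target$start &
        near$strand == on_target$strand)
}

#' Perfect-match reactivity of a spacer in another species' genome
#'
#' @param spacer 20-nt spacer.
#' @param species_genome Named character vector of contigs.
#' @return `TRUE` iff at least one 0-mismatch site with an NGG PAM exists on
#'   either strand.
#' @export
species_reactive <- function(spacer, species_genome) {
  nrow(scan_offtargets(spacer, species_genome, max_mismatches = 0L, pam = "NGG")) > 0
}

#' Load the CFD penalty tables
#'
#' Returns the mismatch-penalty and PAM-penalty tables used by
#' [cfd_score()]. The tables shipped with the package
#' (`cfd_penalty_synthetic.tsv`, `cfd_pam_synthetic.tsv`) are synthetic
#' stand-ins with the real schema — smoothly position- and
#' mismatch-type-dependent activity fractions, not the published empirical
#' values — so any table with the same columns can be swapped in.
#'
#' @param mismatch_path,pam_path Optional paths to alternative TSV tables.
#' @return List with elements `mismatch` (tibble: `position`, `guide_base`,
#'   `site_base`, `penalty`) and `pam` (tibble: `dinucleotide`, `penalty`).
#' @export
load_cfd_tables <- function(mismatch_path = NULL, pam_path = NULL) {
  mismatch_path <- mismatch_path %||%
    system.file("extdata", "cfd_penalty_synthetic.tsv", package = "guidescreen")
  pam_path <- pam_path %||%
    system.file("extdata", "cfd_pam_synthetic.tsv", package = "guidescreen")
  list(
    mismatch = tibble::as_tibble(utils::read.delim(mismatch_path, comment.char = "#")),
    pam = tibble::as_tibble(utils::read.delim(pam_path, comment.char = "#"))
  )
}

#' Load the MIT position-weight vector
#'
#' The 20 per-position mismatch weights of the MIT specificity score
#' (Hsu et al. 2013), PAM-distal position 1 to PAM-proximal position 20.
#'
#' @param path Optional path to an alternative TSV (columns `position`,
#'   `weight`).
#' @return Numeric vector of length 20.
#' @export
load_mit_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mit_weights.tsv", package = "guidescreen")
  tab <- utils::read.delim(path, comment.char = "#")
  stopifnot(nrow(tab) == 20L)
  tab$weight[order(tab$position)]
}

#' CFD score of off-target hits
#'
#' Cutting frequency determination: the product over mismatched positions
#' of per-(position, guide base, site base) activity fractions, times a PAM
#' penalty looked up by the last two PAM bases. A perfect match with an NGG
#' PAM scores exactly 1.
#'
#' @param hits Tibble from [scan_offtargets()].
#' @param tables Penalty tables from [load_cfd_tables()].
#' @return Numeric vector in `[0, 1]`, one score per hit.
#' @export
cfd_score <- function(hits, tables = load_cfd_tables()) {
  mm_tab <- tables$mismatch
  key <- paste(mm_tab$position, mm_tab$guide_base, mm_tab$site_base)
  pen <- stats::setNames(mm_tab$penalty, key)
  pam_pen <- stats::setNames(tables$pam$penalty, tables$pam$dinucleotide)
  vapply(seq_len(nrow(hits)), function(i) {
    det <- hits$mismatches[[i]]
    p <- 1
    if (nrow(det) > 0) {
      k <- paste(det$position, det$guide_base, det$site_base)
      miss <- is.na(pen[k])
      if (any(miss)) {
        rlang::abort(paste0("no CFD penalty entry for (position, guide, site) = (",
                            k[miss][1], ")"),
                     class = "guidescreen_parameter_error")
      }
      p <- prod(pen[k])
    }
    dinuc <- substr(hits$pam_observed[i], 2L, 3L)
    if (is.na(pam_pen[dinuc])) {
      rlang::abort(paste0("no CFD PAM penalty entry for ", dinuc),
                   class = "guidescreen_parameter_error")
    }
    p * unname(pam_pen[dinuc])
  }, numeric(1))
}

#' MIT per-hit and aggregate specificity scores
#'
#' Per hit with `m` mismatches at positions `p`: `100 x prod(1 - w[p]) x
#' 1 / (((19 - dbar) / 19) * 4 + 1) x 1 / m^2`, where `dbar` is the mean
#' pairwise distance between mismatch positions (`dbar = 19` when `m <= 1`).
#' A perfect match scores 100 and is treated as the on-target, so it is
#' excluded from the aggregate's off-target sum. The aggregate guide score
#' is `100 x 100 / (100 + sum(per-hit))` over off-target hits: 100 with no
#' off-targets, strictly decreasing as hits are added.
#'
#' @param hits Tibble from [scan_offtargets()].
#' @param weights Position-weight vector from [load_mit_weights()].
#' @return List with `per_hit` (numeric vector, 0-100) and `aggregate`
#'   (scalar, 0-100).
#' @export
mit_scores <- function(hits, weights = load_mit_weights()) {
  stopifnot(length(weights) == 20L)
  per_hit <- vapply(seq_len(nrow(hits)), function(i) {
    det <- hits$mismatches[[i]]
    m <- nrow(det)
    if (m == 0L) return(100)
    dbar <- if (m == 1L) 19 else mean(stats::dist(det$position))
    100 * prod(1 - weights[det$position]) *
      (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / m^2)
  }, numeric(1))
  offtarget <- hits$mismatch_count > 0L
  list(per_hit = per_hit,
       aggregate = 100 * 100 / (100 + sum(per_hit[offtarget])))
}

#' Aggregate CFD specificity score
#'
#' Defined analogously to the MIT aggregate, as this package's convention:
#' `100 x 100 / (100 + sum(100 x cfd))` over off-target (imperfect) hits.
#'
#' @inheritParams cfd_score
#' @return Scalar in `(0, 100]`.
#' @export
cfd_specificity <- function(hits, tables = load_cfd_tables()) {
  offtarget <- hits$mismatch_count > 0L
  if (!any(offtarget)) return(100)
  100 * 100 / (100 + sum(100 * cfd_score(hits[offtarget, ], tables)))
}

#' Classify the genomic context of off-target hits
#'
#' @param hits Tibble from [scan_offtargets()].
#' @param exons Tibble of exon intervals (`contig`, `start`, `end`, 1-based
#'   inclusive).
#' @param genes Tibble of whole-gene spans, same columns.
#' @return Character vector: `"exonic"` if the hit footprint overlaps any
#'   exon (a single shared base counts), else `"intronic"` if inside a gene
#'   span, else `"intergenic"`.
#' @export
classify_context <- function(hits, exons, genes) {
  overlaps_any <- function(i, tab) {
    any(tab$contig == hits$contig[i] &
          tab$start <= hits$end[i] & hits$start[i] <= tab$end)
  }
  vapply(seq_len(nrow(hits)), function(i) {
    if (overlaps_any(i, exons)) "exonic"
    else if (overlaps_any(i, genes)) "intronic"
    else "intergenic"
  }, character(1))
}

#' Off-target scan restricted to paralog coding regions
#'
#' Scans at a relaxed mismatch tolerance (default 4, NRG PAM) and keeps only
#' hits whose footprint overlaps the provided paralog CDS intervals —
#' the check that a guide cannot cross-react with the coding sequence of a
#' paralogous gene.
#'
#' @param spacer 20-nt spacer.
#' @param genome Named character vector of contigs.
#' @param paralog_cds Tibble of paralog CDS intervals (`contig`, `start`,
#'   `end`, 1-based inclusive).
#' @param max_mismatches Mismatch tolerance (default 4).
#' @param pam PAM pattern (default `"NRG"`).
#' @return Tibble of hits in paralog CDS regions (possibly empty).
#' @export
paralog_check <- function(spacer, genome, paralog_cds, max_mismatches = 4L,
                          pam = "NRG") {
  hits <- scan_offtargets(spacer, genome, max_mismatches, pam)
  if (nrow(hits) == 0) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    any(paralog_cds$contig == hits$contig[i] &
          paralog_cds$start <= hits$end[i] & hits$start[i] <= paralog_cds$end)
  }, logical(1))
  hits[keep, ]
}

#' Full specificity report for a set of guides
#'
#' Runs the off-target scan for each guide, identifies the on-target hit as
#' the one whose footprint equals the guide's design interval, and
#' summarizes specificity: near-hit count, the likely-specific call, MIT and
#' CFD aggregate scores, and perfect-match reactivity in any comparator
#' species genomes supplied.
#'
#' @param guides Tibble with at least `spacer`, `contig`, `start`, `strand`
#'   (e.g. from [enumerate_protospacers()] or [apply_design_filter()]).
#' @param genome Named character vector of contigs.
#' @param species Optional named list of comparator genomes; adds one
#'   logical `reactive_<name>` column per genome.
#' @param max_mismatches,pam Scan parameters (defaults 2, `"NRG"`).
#' @param cfd_tables,mit_weights Score inputs.
#' @return The guide tibble with `hits` (list column), `n_offtargets`
#'   (off-target hits at `<= max_mismatches` mismatches), `likely_specific`,
#'   `mit_specificity`, `cfd_spec` and any species columns appended.
#' @export
specificity_report <- function(guides, genome, species = list(),
                               max_mismatches = 2L, pam = "NRG",
                               cfd_tables = load_cfd_tables(),
                               mit_weights = load_mit_weights()) {
  res <- lapply(seq_len(nrow(guides)), function(i) {
    guide_hits <- scan_offtargets(guides$spacer[i], genome, max_mismatches, pam)
    on_target <- list(contig = guides$contig[i], start = guides$start[i],
                      strand = guides$strand[i])
    is_on <- guide_hits$contig == on_target$contig &
      guide_hits$start == on_target$start & guide_hits$strand == on_target$strand
    off <- guide_hits[!is_on | guide_hits$mismatch_count > 0L, ]
    tibble::tibble(
      hits = list(guide_hits),
      n_offtargets = sum(!is_on),
      likely_specific = is_likely_specific(guide_hits, on_target, mm_threshold = 2L),
      mit_specificity = mit_scores(off, mit_weights)$aggregate,
      cfd_spec = cfd_specificity(off, cfd_tables)
    )
  })
  out <- dplyr::bind_cols(guides, dplyr::bind_rows(res))
  for (sp in names(species)) {
    out[[paste0("reactive_", sp)]] <-
      vapply(out$spacer, species_reactive, logical(1),
             species_genome = species[[sp]], USE.NAMES = FALSE)
  }
  out
}
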