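# Protospacer enumeration and guide annotation against a spliced gene model.
#
# Cut-site convention: the SpCas9 blunt cut sits between protospacer
# positions 17 and 18, i.e. 3 nt 5' of the PAM. `cut_site` reports the
# 1-based genomic position of protospacer position 17 (the base 5' of the
# cut on the protospacer strand). For projection onto the CDS the
# "nucleotide to the left of the cut" is resolved in coding-strand
# orientation: the indexed base is the CDS-5' neighbor of the cut junction,
# so for guides antisense to the coding strand it is the base on the other
# side of the junction from protospacer position 17.

#' Enumerate candidate protospacers in a genomic window
#'
#' Scans every 23-nt window of the region on one or both strands and
#' reports each window whose last three bases match the PAM pattern.
#' Windows containing an `N` anywhere never match.
#'
#' @param genome Named character vector of contigs (see [read_fasta()]).
#' @param contig Contig to scan.
#' @param start,end 1-based inclusive bounds of the scan region; default the
#'   whole contig. Only windows fully inside the region are reported.
#' @param pam IUPAC PAM pattern (default `"NGG"`, the canonical SpCas9 PAM).
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return Tibble with one row per site: `site_id`, `spacer` (20 nt, written
#'   5'->3' on the protospacer strand), `pam`, `contig`, `start`, `end`
#'   (1-based inclusive, 23-nt footprint), `strand`, `cut_site` (1-based
#'   genomic position of protospacer position 17), sorted by `start` then
#'   strand.
#' @export
enumerate_protospacers <- function(genome, contig, start = NULL, end = NULL,
                                   pam = "NGG", both_strands = TRUE) {
  seq <- genome[[contig]]
  if (is.null(seq)) {
    rlang::abort(paste0("contig ", contig, " absent from genome"),
                 class = "guidescreen_io_error")
  }
  L <- nchar(seq)
  start <- start %||% 1L
  end <- end %||% L
  if (start < 1L || end > L || start > end) {
    rlang::abort("scan region out of contig bounds", class = "guidescreen_parameter_error")
  }
  pam_letters <- .check_iupac(pam)
  if (length(pam_letters) != 3L) {
    rlang::abort("PAM pattern must be 3 nt", class = "guidescreen_parameter_error")
  }
  region <- substr(seq, start, end)
  chars <- .seq_chars(region)
  off <- start - 1L  # 0-based offset of region within contig

  plus_starts <- .pam_window_starts(chars, pam_letters) + off
  sites <- list(.sites_from_starts(seq, plus_starts, "+", contig))
  if (both_strands) {
    rc_chars <- rev(chartr("ACGTN", "TGCAN", chars))
    rc_starts <- .pam_window_starts(rc_chars, pam_letters)
    minus_starts <- (length(chars) - (rc_starts + 23L)) + off
    sites[[2]] <- .sites_from_starts(seq, minus_starts, "-", contig)
  }
  out <- dplyr::bind_rows(sites)
  out <- out[order(out$start, out$strand), ]
  out$site_id <- sprintf("ps%04d", seq_len(nrow(out)))
  tibble::as_tibble(out[, c("site_id", "spacer", "pam", "contig", "start", "end",
                            "strand", "cut_site")])
}

# Build site rows from 0-based 23-nt window starts.
.sites_from_starts <- function(seq, starts, strand, contig) {
  if (length(starts) == 0) {
    return(tibble::tibble(spacer = character(0), pam = character(0),
                          contig = character(0), start = integer(0), end = integer(0),
                          strand = character(0), cut_site = integer(0)))
  }
  window <- substring(seq, starts + 1L, starts + 23L)
  if (strand == "+") {
    spacer <- substr(window, 1L, 20L)
    pam <- substr(window, 21L, 23L)
    cut_site <- starts + 17L            # 1-based position of protospacer pos 17
  } else {
    rc <- revcomp(window)
    spacer <- substr(rc, 1L, 20L)
    pam <- substr(rc, 21L, 23L)
    cut_site <- starts + 7L             # plus-coord of protospacer pos 17
  }
  tibble::tibble(spacer = spacer, pam = pam, contig = contig,
                 start = as.integer(starts + 1L), end = as.integer(starts + 23L),
                 strand = strand, cut_site = as.integer(cut_site))
}

# 0-based cut junction (number of plus-strand bases left of the blunt cut)
# from the 1-based site start and strand.
.cut_junction <- function(start1, strand) {
  s0 <- start1 - 1L
  ifelse(strand == "+", s0 + 17L, s0 + 6L)
}

#' Classify which isoforms a cut position disrupts
#'
#' @param pos Integer vector of 0-based genomic positions (cut-indexed
#'   nucleotides).
#' @param model A `gene_model` with at least the long isoform.
#' @param long_isoform,short_isoform Isoform ids; defaults: the longest CDS
#'   and the shortest CDS in the model.
#' @return Character vector: `"dual"` (cut inside both CDSs), `"long_only"`
#'   (only the long CDS), or `"none"`.
#' @export
classify_isoform_targeting <- function(pos, model,
                                       long_isoform = longest_isoform(model),
                                       short_isoform = shortest_isoform(model)) {
  in_long <- !is.na(project_genomic_to_cds(pos, model, long_isoform))
  if (identical(short_isoform, long_isoform)) {
    return(ifelse(in_long, "long_only", "none"))
  }
  in_short <- !is.na(project_genomic_to_cds(pos, model, short_isoform))
  dplyr::case_when(in_long & in_short ~ "dual",
                   in_long ~ "long_only",
                   .default = "none")
}

#' Id of the shortest isoform
#' @param model A `gene_model`.
#' @return Isoform id.
#' @export
shortest_isoform <- function(model) {
  lens <- vapply(model$isoforms, function(iv) sum(iv$end - iv$start), numeric(1))
  names(which.min(lens))
}

#' Find in-frame near-cognate start codons in the 5' CDS
#'
#' Scans the first `search_window_nt` nucleotides of a spliced CDS for
#' in-frame occurrences of the given codons (default `CTG`, whose transcript
#' counterpart CUG can initiate translation with near-cognate efficiency).
#' A guide cutting 5' of such a codon risks leaving a truncated,
#' re-initiated protein intact.
#'
#' @param cds_sequence Spliced CDS nucleotide string.
#' @param codons Character vector of DNA codons to search (default `"CTG"`).
#' @param search_window_nt Only positions up to this bound are reported
#'   (default 450 nt = 150 codons).
#' @return Integer vector of 1-based CDS nucleotide positions `p` with
#'   `p %% 3 == 1` where a listed codon starts.
#' @export
scan_inframe_near_cognate <- function(cds_sequence, codons = "CTG",
                                      search_window_nt = 450L) {
  n <- nchar(cds_sequence)
  if (search_window_nt > n) search_window_nt <- n
  starts <- seq.int(1L, search_window_nt, by = 3L)
  starts <- starts[starts + 2L <= n]
  found <- substring(cds_sequence, starts, starts + 2L) %in% toupper(codons)
  starts[found]
}

#' Annotate protospacer sites with cut-site, codon and isoform information
#'
#' Adds to each site: `cut_cds_index` (1-based spliced-CDS position of the
#' cut-indexed nucleotide on the long isoform; when the cut falls between
#' two codons the N-terminal codon is indexed), `codon_index`
#' (`ceiling(cut_cds_index / 3)`), `exon` (1-based exon number in
#' transcription order), `isoform_targeting`, and — when `genome` is given —
#' `upstream_of_inframe_cug`, flagging guides whose cut lies 5' of an
#' in-frame near-cognate start codon in the search window. Guides whose cut
#' indexes codon `max_codon - 1` or `max_codon` are flagged
#' `boundary_codon` since "before codon `max_codon`" is boundary-sensitive.
#'
#' @param sites Tibble from [enumerate_protospacers()].
#' @param model A `gene_model`.
#' @param genome Optional genome for the near-cognate start-codon scan.
#' @param cug_codons,cug_window_nt Passed to [scan_inframe_near_cognate()].
#' @param max_codon Codon bound used only for the `boundary_codon` flag
#'   (default 980).
#' @return The input tibble with annotation columns appended.
#' @export
annotate_guides <- function(sites, model, genome = NULL, cug_codons = "CTG",
                            cug_window_nt = 450L, max_codon = 980L) {
  junction <- .cut_junction(sites$start, sites$strand)
  indexed <- if (model$strand == "+") junction - 1L else junction
  long <- longest_isoform(model)
  cds_idx <- project_genomic_to_cds(indexed, model, long)
  out <- dplyr::mutate(
    sites,
    cut_cds_index = cds_idx,
    codon_index = as.integer(ceiling(cds_idx / 3)),
    exon = exon_number(indexed, model),
    isoform_targeting = classify_isoform_targeting(indexed, model),
    boundary_codon = !is.na(.data$codon_index) &
      .data$codon_index %in% c(max_codon - 1L, max_codon)
  )
  if (!is.null(genome)) {
    cds_seq <- spliced_cds_sequence(model, genome, long)
    cug <- scan_inframe_near_cognate(cds_seq, cug_codons, cug_window_nt)
    out$upstream_of_inframe_cug <- !is.na(out$cut_cds_index) & length(cug) > 0 &
      vapply(out$cut_cds_index, function(ci) isTRUE(any(ci < cug)), logical(1))
  }
  out
}

#' Apply the design filter and collapse duplicate spacers
#'
#' Keeps a site iff its cut codon is strictly before `max_codon` and it is
#' either reactive in the comparator species or both classified likely
#' specific and located in the fallback exon (default exon 2). Sites
#' sharing a spacer sequence are collapsed to one guide that retains every
#' targeting location in a `locations` list column; guide ids `cg001...`
#' are assigned in genomic order of the primary (first) location. The
#' filter is idempotent and order-independent.
#'
#' @param sites Annotated tibble from [annotate_guides()].
#' @param specificity Named logical vector or data frame
#'   (`spacer`, `likely_specific`) keyed by spacer sequence.
#' @param species Named logical vector or data frame
#'   (`spacer`, `species_match`): perfect-match reactivity in the
#'   comparator species genome.
#' @param max_codon Exclusive codon bound (default 980: codons `<= 979`
#'   pass).
#' @param fallback_exon Exon whose likely-specific guides are rescued when
#'   not species-reactive (default 2).
#' @return Tibble with one row per unique spacer: `guide_id`, `spacer`,
#'   primary location columns, annotation columns, `n_locations` and
#'   `locations` (list of tibbles).
#' @export
apply_design_filter <- function(sites, specificity, species,
                                max_codon = 980L, fallback_exon = 2L) {
  spec_flags <- .flag_lookup(specificity, c("likely_specific", "flag"))
  spp_flags <- .flag_lookup(species, c("species_match", "flag"))
  missing_spec <- setdiff(unique(sites$spacer), names(spec_flags))
  if (length(missing_spec) > 0) {
    rlang::abort(paste0("no specificity flag for spacer ", missing_spec[1]),
                 class = "guidescreen_parameter_error")
  }
  missing_spp <- setdiff(unique(sites$spacer), names(spp_flags))
  if (length(missing_spp) > 0) {
    rlang::abort(paste0("no species flag for spacer ", missing_spp[1]),
                 class = "guidescreen_parameter_error")
  }
  keep <- !is.na(sites$codon_index) & sites$codon_index < max_codon &
    (spp_flags[sites$spacer] |
       (spec_flags[sites$spacer] & !is.na(sites$exon) & sites$exon == fallback_exon))
  kept <- sites[keep, ]
  if (nrow(kept) == 0) {
    return(dplyr::mutate(kept, guide_id = character(0), n_locations = integer(0),
                         locations = list()))
  }
  kept <- kept[order(kept$start, kept$strand), ]
  loc_cols <- intersect(c("site_id", "contig", "start", "end", "strand", "cut_site",
                          "cut_cds_index", "codon_index", "exon"), names(kept))
  grouped <- dplyr::group_by(kept, .data$spacer)
  collapsed <- dplyr::summarise(
    grouped,
    locations = list(dplyr::pick(dplyr::all_of(loc_cols))),
    n_locations = dplyr::n(),
    dplyr::across(dplyr::all_of(setdiff(names(kept), "spacer")), dplyr::first),
    .groups = "drop"
  )
  collapsed <- collapsed[order(collapsed$start, collapsed$strand), ]
  collapsed$guide_id <- sprintf("cg%03d", seq_len(nrow(collapsed)))
  dplyr::relocate(collapsed, "guide_id")
}

.flag_lookup <- function(x, value_cols) {
  if (is.data.frame(x)) {
    col <- intersect(value_cols, names(x))[1]
    if (is.na(col) || !"spacer" %in% names(x)) {
      rlang::abort("flag table needs columns spacer and likely_specific/species_match",
                   class = "guidescreen_parameter_error")
    }
    stats::setNames(as.logical(x[[col]]), x$spacer)
  } else if (is.logical(x) && !is.null(names(x))) {
    x
  } else {
    rlang::abort("flags must be a named logical vector or a data frame",
                 class = "guidescreen_parameter_error")
  }
}
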