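# Editing-outcome quantification from amplicon reads: global alignment of
# each read to its reference amplicon, indel calling in a small
# quantification window at the cut site, and screen-level summaries.

#' Define an amplicon quantification assay
#'
#' Locates the guide's protospacer on the amplicon (exactly one occurrence
#' on either strand is required) and fixes the quantification window. With
#' the defaults — center offset -3 from the PAM-proximal protospacer end
#' and window size 1 — the window is the single amplicon base 5' of the
#' blunt cut. A window of size `w` covers the `w` amplicon positions
#' nearest the cut junction (`ceiling(w/2)` to its left, `floor(w/2)` to
#' its right, in amplicon coordinates).
#'
#' @param amplicon Reference amplicon sequence (typically 300-450 nt).
#' @param spacer 20-nt protospacer of the guide.
#' @param guide_id Optional guide identifier carried into outputs.
#' @param window_size Quantification window width in nt (default 1).
#' @param center_offset Offset of the cut junction from the PAM-proximal
#'   protospacer end (default -3, the SpCas9 blunt cut).
#' @param min_homology Minimum percent alignment identity for a read to be
#'   quantified (default 70).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (defaults
#'   +2/-1/6/1, end-to-end).
#' @return An object of class `amplicon_assay`.
#' @export
amplicon_assay <- function(amplicon, spacer, guide_id = NULL, window_size = 1L,
                           center_offset = -3L, min_homology = 70,
                           match = 2, mismatch = -1, gap_open = 6, gap_extend = 1) {
  amplicon <- toupper(amplicon); spacer <- toupper(spacer)
  stopifnot(nchar(spacer) == 20L)
  fwd <- gregexpr(spacer, amplicon, fixed = TRUE)[[1]]
  rev <- gregexpr(revcomp(spacer), amplicon, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0]; rev <- rev[rev > 0]
  n_occ <- length(fwd) + length(rev)
  if (n_occ != 1L) {
    rlang::abort(paste0("protospacer must occur exactly once in the amplicon (found ",
                        n_occ, ")"),
                 class = "guidescreen_parameter_error")
  }
  if (length(fwd) == 1L) {
    strand <- "+"
    s0 <- fwd - 1L                       # 0-based spacer start
    junction <- s0 + 20L + center_offset # bases left of the cut
  } else {
    strand <- "-"
    s0 <- rev - 1L
    junction <- s0 - center_offset
  }
  lo <- junction - as.integer(ceiling(window_size / 2)) + 1L
  hi <- junction + as.integer(floor(window_size / 2))
  if (lo < 1L || hi > nchar(amplicon)) {
    rlang::abort("quantification window outside amplicon bounds",
                 class = "guidescreen_parameter_error")
  }
  structure(
    list(amplicon = amplicon, spacer = spacer, guide_id = guide_id,
         guide_strand = strand, cut_junction = junction,
         window = c(lo, hi), min_homology = min_homology,
         scoring = list(match = match, mismatch = mismatch,
                        gap_open = gap_open, gap_extend = gap_extend)),
    class = "amplicon_assay"
  )
}

#' @export
print.amplicon_assay <- function(x, ...) {
  cat("<amplicon_assay>", x$guide_id %||% "", nchar(x$amplicon), "nt amplicon;",
      "guide on", x$guide_strand, "strand; cut junction after base", x$cut_junction,
      "; window", paste(x$window, collapse = "-"), "\n")
  invisible(x)
}

# Substitution matrix over A,C,G,T,N where N never matches anything.
.subst_matrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m
}

#' Align reads end-to-end to an assay's amplicon
#'
#' Global (Needleman-Wunsch) alignment of each read to the amplicon; read
#' orientation is auto-detected by aligning both the read and its reverse
#' complement and keeping the higher score. Identity is
#' `matches / aligned columns x 100`, gap columns included. Duplicate read
#' sequences are aligned once and the calls reused.
#'
#' Gap placement within a repeat is ambiguous, so each indel also carries
#' its range of equivalent placements: `j_left`/`j_right` for insertions
#' (leftmost/rightmost equivalent junction), `left_start`/`right_end` for
#' deletions (span of all equivalent deleted segments).
#'
#' @param assay An [amplicon_assay()].
#' @param reads Character vector of read sequences (names become read ids).
#' @return Tibble with one row per read: `read_id`, `orientation`, `score`,
#'   `identity`, and list columns `deletions` (amplicon `start`, `end`,
#'   1-based inclusive, `width`, `left_start`, `right_end`) and
#'   `insertions` (`junction` = amplicon position left of the inserted
#'   bases, `width`, `j_left`, `j_right`).
#' @export
align_reads <- function(assay, reads) {
  stopifnot(inherits(assay, "amplicon_assay"), length(reads) > 0)
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  reads <- gsub("[^ACGT]", "N", toupper(reads))
  uq <- unique(reads)
  map <- match(reads, uq)
  sm <- .subst_matrix(assay$scoring$match, assay$scoring$mismatch)
  subject <- Biostrings::DNAString(assay$amplicon)
  fwd_set <- Biostrings::DNAStringSet(uq)
  rev_set <- Biostrings::reverseComplement(fwd_set)
  align <- function(set) Biostrings::pairwiseAlignment(
    set, subject, type = "global", substitutionMatrix = sm,
    gapOpening = assay$scoring$gap_open, gapExtension = assay$scoring$gap_extend)
  aln_f <- align(fwd_set); aln_r <- align(rev_set)
  use_rev <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
  sel <- function(f, r) ifelse(use_rev, r, f)
  score <- sel(Biostrings::score(aln_f), Biostrings::score(aln_r))
  nm <- sel(Biostrings::nmatch(aln_f), Biostrings::nmatch(aln_r))
  nmm <- sel(Biostrings::nmismatch(aln_f), Biostrings::nmismatch(aln_r))
  del_l <- as.list(Biostrings::deletion(aln_f))   # subject (amplicon) coords
  ins_l <- as.list(Biostrings::insertion(aln_f))  # pattern (read) coords
  if (any(use_rev)) {
    del_r <- as.list(Biostrings::deletion(aln_r))
    ins_r <- as.list(Biostrings::insertion(aln_r))
    del_l[use_rev] <- del_r[use_rev]
    ins_l[use_rev] <- ins_r[use_rev]
  }
  amp_chars <- .seq_chars(assay$amplicon)
  empty_del <- .quick_df(start = integer(0), end = integer(0), width = integer(0),
                         left_start = integer(0), right_end = integer(0))
  empty_ins <- .quick_df(junction = integer(0), width = integer(0),
                         j_left = integer(0), j_right = integer(0))
  gapw <- numeric(length(uq))
  deletions <- vector("list", length(uq))
  insertions <- vector("list", length(uq))
  for (i in seq_along(uq)) {
    del <- del_l[[i]]; ins <- ins_l[[i]]
    nd <- length(del); ni <- length(ins)
    if (nd == 0L && ni == 0L) {
      deletions[[i]] <- empty_del; insertions[[i]] <- empty_ins
      next
    }
    oriented <- if (use_rev[i]) revcomp(uq[i]) else uq[i]
    ds <- IRanges::start(del); de <- IRanges::end(del)
    dw <- de - ds + 1L
    is <- IRanges::start(ins); iw <- IRanges::width(ins)
    gapw[i] <- sum(dw) + sum(iw)
    # equivalent-placement range of each deletion
    ls <- ds; re <- de
    for (k in seq_len(nd)) {
      while (ls[k] > 1L && amp_chars[re[k] - (ds[k] - ls[k])] == amp_chars[ls[k] - 1L]) {
        ls[k] <- ls[k] - 1L
      }
      while (re[k] < length(amp_chars) &&
             amp_chars[ds[k] + (re[k] - de[k])] == amp_chars[re[k] + 1L]) {
        re[k] <- re[k] + 1L
      }
    }
    deletions[[i]] <- .quick_df(start = ds, end = de, width = dw,
                                left_start = ls, right_end = re)
    if (ni > 0L) {
      junction <- integer(ni); jl <- integer(ni); jr <- integer(ni)
      for (k in seq_len(ni)) {
        j <- .ins_junction(is[k], is, iw, ds, dw)
        s_chars <- .seq_chars(substr(oriented, is[k], is[k] + iw[k] - 1L))
        # shift left while the segment's last base equals the base at the
        # junction; shift right while its first base equals the next base
        sl <- s_chars; j_left <- j
        while (j_left >= 1L && length(sl) > 0L && sl[length(sl)] == amp_chars[j_left]) {
          sl <- c(amp_chars[j_left], sl[-length(sl)])
          j_left <- j_left - 1L
        }
        sr <- s_chars; j_right <- j
        while (j_right < length(amp_chars) && length(sr) > 0L &&
               sr[1L] == amp_chars[j_right + 1L]) {
          sr <- c(sr[-1L], amp_chars[j_right + 1L])
          j_right <- j_right + 1L
        }
        junction[k] <- j; jl[k] <- j_left; jr[k] <- j_right
      }
      insertions[[i]] <- .quick_df(junction = junction, width = iw,
                                   j_left = jl, j_right = jr)
    } else {
      insertions[[i]] <- empty_ins
    }
  }
  identity <- 100 * nm / (nm + nmm + gapw)
  tibble::tibble(
    read_id = ids,
    orientation = ifelse(use_rev, "-", "+")[map],
    score = score[map],
    identity = identity[map],
    deletions = deletions[map],
    insertions = insertions[map]
  )
}

.quick_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

# Amplicon position left of an insertion whose read coordinates start at
# `a`, given all insertion starts/widths (read coords) and deletion
# starts/widths (amplicon coords). Earlier insertions shift read
# coordinates; earlier deletions shift amplicon coordinates; iterate to a
# fixpoint.
.ins_junction <- function(a, ins_start, ins_width, del_start, del_width) {
  j0 <- (a - 1L) - sum(ins_width[ins_start < a])
  j <- j0
  repeat {
    jn <- j0 + sum(del_width[del_start <= j])
    if (jn == j) return(as.integer(j))
    j <- jn
  }
}

#' Call the editing outcome of each read
#'
#' Reads with identity below the assay's homology floor are discarded. A
#' kept read is `modified` iff at least one inserted or deleted base
#' overlaps the quantification window (insertions are assigned to the
#' junction position left of the inserted bases); substitutions alone leave
#' a read `unmodified`. `net_indel` sums signed lengths of
#' window-overlapping indels, and a read is a frameshift iff it is modified
#' with `net_indel` not divisible by 3.
#'
#' @param assay An [amplicon_assay()].
#' @param reads Character vector of read sequences.
#' An indel overlaps the window when any of its equivalent gap placements
#' does: a deletion if the union span of its equivalent segments intersects
#' the window, an insertion if any equivalent junction lies inside it.
#'
#' @return Tibble per read: `read_id`, `status` (`unmodified`, `modified`,
#'   `discarded_low_homology`), `identity`, `net_indel`, `frameshift`.
#' @export
call_edits <- function(assay, reads) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  reads <- gsub("[^ACGT]", "N", toupper(reads))
  uq <- unique(reads)
  map <- match(reads, uq)
  aln <- align_reads(assay, uq)
  lo <- assay$window[1]; hi <- assay$window[2]
  net <- integer(length(uq)); modified <- logical(length(uq))
  for (i in seq_along(uq)) {
    del <- aln$deletions[[i]]; ins <- aln$insertions[[i]]
    if (nrow(del) + nrow(ins) == 0L) next
    del_in <- del$left_start <= hi & lo <= del$right_end
    ins_in <- ins$j_right >= lo & ins$j_left <= hi
    net[i] <- sum(ins$width[ins_in]) - sum(del$width[del_in])
    modified[i] <- any(del_in) || any(ins_in)
  }
  discarded <- aln$identity < assay$min_homology
  tibble::tibble(
    read_id = ids,
    status = dplyr::case_when(discarded ~ "discarded_low_homology",
                              modified ~ "modified",
                              .default = "unmodified")[map],
    identity = aln$identity[map],
    net_indel = ifelse(discarded, NA_integer_, net)[map],
    frameshift = (!discarded & modified & net %% 3L != 0L)[map]
  )
}

#' Quantify indel and frameshift rates for one assay
#'
#' @param assay An [amplicon_assay()].
#' @param reads Character vector of read sequences.
#' @return One-row tibble: `guide_id`, `n_reads`, `n_discarded`, `n_used`,
#'   `n_modified`, `n_frameshift`, `indel_rate`, `frameshift_rate`. With
#'   zero usable reads the rates are `NA` (an explicit no-data result, not
#'   0).
#' @export
quantify_edits <- function(assay, reads) {
  calls <- call_edits(assay, reads)
  used <- calls[calls$status != "discarded_low_homology", ]
  n_used <- nrow(used)
  tibble::tibble(
    guide_id = assay$guide_id %||% NA_character_,
    n_reads = nrow(calls),
    n_discarded = nrow(calls) - n_used,
    n_used = n_used,
    n_modified = sum(used$status == "modified"),
    n_frameshift = sum(used$frameshift),
    indel_rate = if (n_used > 0) sum(used$status == "modified") / n_used else NA_real_,
    frameshift_rate = if (n_used > 0) sum(used$frameshift) / n_used else NA_real_
  )
}

#' Summarize a screen across replicates
#'
#' Computes per-group mean and sample SD of indel and frameshift rates and
#' a dense rank by mean frameshift rate (rank 1 = highest), with ties
#' broken by spacer sequence (or guide id when no spacer column exists).
#'
#' @param results Tibble of per-replicate [quantify_edits()] rows (plus any
#'   condition columns).
#' @param ... Grouping columns (tidy-eval), e.g. `guide_id, dose`.
#' @return Tibble with `mean_indel`, `sd_indel`, `mean_frameshift`,
#'   `sd_frameshift`, `n_replicates` and `rank` per group. SDs are `NA`
#'   with a single replicate.
#' @export
summarize_screen <- function(results, ...) {
  grouped <- dplyr::group_by(results, ...)
  tie_col <- if ("spacer" %in% names(results)) "spacer" else "guide_id"
  out <- dplyr::summarise(
    grouped,
    mean_indel = mean(.data$indel_rate),
    sd_indel = stats::sd(.data$indel_rate),
    mean_frameshift = mean(.data$frameshift_rate),
    sd_frameshift = stats::sd(.data$frameshift_rate),
    n_replicates = dplyr::n(),
    tie_key = dplyr::first(.data[[tie_col]]),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_frameshift), .data$tie_key)
  out$rank <- seq_len(nrow(out))
  dplyr::select(out, -"tie_key")
}

#' Compare per-guide editing rates between two conditions
#'
#' Ordinary least-squares fit and Pearson correlation of paired per-guide
#' rates (e.g. frameshift rate in T cells vs macrophages, or frameshift
#' rate vs protein loss).
#'
#' @param data Tibble with one row per guide.
#' @param x,y Columns (tidy-eval) holding the paired rates.
#' @return An `editing_concordance` object; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance].
#' @export
compare_conditions <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  if (sum(ok) < 3) {
    rlang::abort("need at least 3 paired guides", class = "guidescreen_parameter_error")
  }
  d <- tibble::tibble(x = xv[ok], y = yv[ok])
  fit <- stats::lm(y ~ x, data = d)
  structure(
    list(fit = fit, data = d,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(d$x, d$y),
         r_squared = summary(fit)$r.squared,
         n = nrow(d)),
    class = "editing_concordance"
  )
}

#' @export
print.editing_concordance <- function(x, ...) {
  cat(sprintf("<editing_concordance> n = %d, slope = %.3f, intercept = %.3f, r = %.3f, r^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Flag guides whose repair outcomes deviate from the frameshift expectation
#'
#' Under a uniform distribution over net indel lengths mod 3, two thirds of
#' modified reads are frameshifts. Each guide's frameshift count among
#' modified reads is tested against 2/3 with a two-sided exact binomial
#' test; a guide is flagged when the deviation is significant and in-frame
#' outcomes are over-represented (observed fraction below 2/3).
#'
#' @param n_frameshift,n_modified Integer vectors of per-guide counts.
#' @param alpha Significance level (default 0.05).
#' @param null_fraction Expected frameshift fraction among modified reads
#'   (default 2/3).
#' @return Tibble: `observed_fraction`, `p_value`, `flagged`.
#' @export
flag_frameshift_deviation <- function(n_frameshift, n_modified, alpha = 0.05,
                                      null_fraction = 2 / 3) {
  stopifnot(length(n_frameshift) == length(n_modified), all(n_frameshift <= n_modified))
  p <- vapply(seq_along(n_modified), function(i) {
    if (n_modified[i] == 0) return(NA_real_)
    stats::binom.test(n_frameshift[i], n_modified[i], p = null_fraction)$p.value
  }, numeric(1))
  obs <- ifelse(n_modified > 0, n_frameshift / n_modified, NA_real_)
  tibble::tibble(observed_fraction = obs, p_value = p,
                 flagged = !is.na(p) & p < alpha & obs < null_fraction)
}

#' Select top candidate guides from a screen summary
#'
#' Applies optional boolean filters, then takes the `k` guides with the
#' highest mean frameshift rate (deterministic given the ranked summary).
#'
#' @param summary Tibble from [summarize_screen()].
#' @param k Number of guides to keep; if more than available, all rows are
#'   returned with a warning.
#' @param ... Filter expressions (tidy-eval), e.g.
#'   `!upstream_of_inframe_cug, likely_specific`.
#' @return Tibble of at most `k` rows, ordered by mean frameshift rate.
#' @export
select_candidates <- function(summary, k, ...) {
  filtered <- dplyr::filter(summary, ...)
  filtered <- dplyr::arrange(filtered, dplyr::desc(.data$mean_frameshift))
  if (k > nrow(filtered)) {
    rlang::warn(paste0("requested ", k, " candidates but only ", nrow(filtered),
                       " pass the filters"))
    k <- nrow(filtered)
  }
  utils::head(filtered, k)
}
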