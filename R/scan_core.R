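# Low-level vectorized window scanning shared by protospacer enumeration
# and mismatch-tolerant off-target search. Sequences are handled as
# character vectors of single bases; any window containing an N is
# disqualified outright (an N never matches a protospacer or PAM position).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.check_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(.IUPAC_SETS))
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid IUPAC letter(s) in pattern: ", paste(bad, collapse = ", ")),
                 class = "guidescreen_parameter_error")
  }
  letters
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# TRUE for each 0-based window start (length = L - width + 1) whose window
# is free of N.
.n_free_windows <- function(chars, width) {
  L <- length(chars)
  nw <- L - width + 1L
  if (nw < 1L) return(logical(0))
  cn <- c(0L, cumsum(chars == "N"))
  (cn[seq_len(nw) + width] - cn[seq_len(nw)]) == 0L
}

# 0-based starts of 23-nt windows whose positions 21..23 match the IUPAC
# PAM pattern and which contain no N.
.pam_window_starts <- function(chars, pam_letters) {
  width <- 20L + length(pam_letters)
  L <- length(chars)
  nw <- L - width + 1L
  if (nw < 1L) return(integer(0))
  ok <- .n_free_windows(chars, width)
  for (j in seq_along(pam_letters)) {
    ok <- ok & chars[(20L + j):(20L + j + nw - 1L)] %in% .IUPAC_SETS[[pam_letters[j]]]
  }
  which(ok) - 1L
}

# Hamming mismatch count of a 20-nt spacer against every window start
# (0-based starts in `starts`) of `chars`.
.window_mismatches <- function(chars, spacer_chars, starts) {
  mm <- integer(length(starts))
  for (i in seq_len(20L)) {
    mm <- mm + (chars[starts + i] != spacer_chars[i])
  }
  mm
}
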