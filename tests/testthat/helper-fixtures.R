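# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive per-window loops, written without any of the package's
# scanning code, so they can serve as ground truth for the vectorized
# implementations.

.fixture_cache <- new.env(parent = emptyenv())

toy_fixture <- function(seed = 42) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- sim_gene_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

# small hand-built two-exon gene on a 60-nt contig, for exact-arithmetic
# tests: exon1 [4,13) fully coding, intron [13,21), exon2 [21,31) with CDS
# [21,24); spliced CDS = "ATGGCTAAG" + "TGA"
tiny_genome <- function() {
  c(chrT = paste0("AAAA", "ATGGCTAAG", "TTTTTTTT", "TGACCCCCCC",
                  strrep("A", 29)))
}

tiny_model <- function() {
  gene_model(
    gene_id = "tiny", contig = "chrT", strand = "+",
    exons = data.frame(start = c(4L, 21L), end = c(13L, 31L)),
    isoforms = list(long = data.frame(start = c(4L, 21L), end = c(13L, 24L)))
  )
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_pam_ok <- function(pam_seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), N = c("A", "C", "G", "T"))
  p <- strsplit(pam_seq, "")[[1]]
  q <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(q), function(i) p[i] %in% sets[[q[i]]], logical(1)))
}

# every 23-nt window on both strands whose tail matches the PAM pattern
oracle_enumerate <- function(seq, pam = "NGG") {
  L <- nchar(seq)
  out <- list()
  for (s in seq_len(L - 22L)) {
    w <- substr(seq, s, s + 22L)
    if (grepl("N", w)) next
    if (oracle_pam_ok(substr(w, 21, 23), pam)) {
      out[[length(out) + 1]] <- data.frame(start = s, strand = "+",
                                           spacer = substr(w, 1, 20))
    }
    wr <- oracle_revcomp(w)
    if (oracle_pam_ok(substr(wr, 21, 23), pam)) {
      out[[length(out) + 1]] <- data.frame(start = s, strand = "-",
                                           spacer = substr(wr, 1, 20))
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(0), strand = character(0),
                                          spacer = character(0)))
  do.call(rbind, out)
}

# naive Hamming off-target scan of one contig, both strands
oracle_scan <- function(spacer, seq, max_mm, pam = "NRG") {
  L <- nchar(seq)
  sp <- strsplit(spacer, "")[[1]]
  out <- list()
  for (s in seq_len(L - 22L)) {
    for (strand in c("+", "-")) {
      w <- substr(seq, s, s + 22L)
      if (strand == "-") w <- oracle_revcomp(w)
      if (grepl("N", w)) next
      if (!oracle_pam_ok(substr(w, 21, 23), pam)) next
      mm <- sum(strsplit(substr(w, 1, 20), "")[[1]] != sp)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(start = s, strand = strand, mm = mm)
      }
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(0), strand = character(0),
                                          mm = integer(0)))
  do.call(rbind, out)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# global affine-gap alignment score by plain dynamic programming
# (Gotoh three-matrix recursion), independent of Biostrings
oracle_nw_score <- function(a, b, match = 2, mismatch = -1,
                            gap_open = 6, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
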