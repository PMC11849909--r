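test_that("off-target scanner equals the brute-force Hamming oracle", {
  spacer <- substr(random_seq(20, 1), 1, 20)
  for (seed in 4:5) {
    seq <- random_seq(2000, seed)
    for (mm in 0:4) {
      got <- scan_offtargets(spacer, c(chr = seq), max_mismatches = mm)
      want <- oracle_scan(spacer, seq, mm)
      want <- want[order(want$start, want$strand), ]
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$strand, want$strand)
      expect_identical(got$mismatch_count, as.integer(want$mm))
    }
  }
})

test_that("planted copies are recovered exactly at the mismatch threshold", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(3000, 11))
  # ensure no accidental near-matches confound the truth
  stopifnot(nrow(scan_offtargets(spacer, genome, 4)) == 0)
  p1 <- plant_site(genome, "chr", 100, spacer, 0, pam = "CGG", seed = 1)
  p2 <- plant_site(p1$genome, "chr", 500, spacer, 1, pam = "TGG", seed = 2)
  p3 <- plant_site(p2$genome, "chr", 900, spacer, 2, pam = "AGG", strand = "-", seed = 3)
  p4 <- plant_site(p3$genome, "chr", 1300, spacer, 3, pam = "GGG", seed = 4)
  hits <- scan_offtargets(spacer, p4$genome, max_mismatches = 2)
  expect_identical(hits$start, c(100L, 500L, 900L))
  expect_identical(hits$mismatch_count, 0:2)
  expect_identical(hits$strand, c("+", "+", "-"))
  # mismatch detail is consistent with the count, PAM never counted
  expect_identical(vapply(hits$mismatches, nrow, integer(1)), 0:2)
  # the relaxed threshold agrees with the oracle on the planted genome
  expect_identical(nrow(scan_offtargets(spacer, p4$genome, 3)),
                   nrow(oracle_scan(spacer, p4$genome[[1]], 3)))
  # a perfect protospacer with a non-NRG PAM is gated out
  p5 <- plant_site(genome, "chr", 2000, spacer, 0, pam = "ATT", seed = 5)
  expect_identical(nrow(scan_offtargets(spacer, p5$genome, 2)), 0L)
})

test_that("likely-specific classification keys on sub-3-mismatch hits only", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(3000, 11))
  on <- plant_site(genome, "chr", 100, spacer, 0, pam = "CGG", seed = 1)
  on_target <- list(contig = "chr", start = 100L, strand = "+")
  hits <- scan_offtargets(spacer, on$genome, 2)
  expect_true(is_likely_specific(hits, on_target))
  # a planted 3-mismatch hit does not break specificity
  p3 <- plant_site(on$genome, "chr", 700, spacer, 3, pam = "AGG", seed = 2)
  expect_true(is_likely_specific(scan_offtargets(spacer, p3$genome, 3), on_target))
  # a planted 2-mismatch hit does
  p2 <- plant_site(on$genome, "chr", 700, spacer, 2, pam = "AGG", seed = 3)
  expect_false(is_likely_specific(scan_offtargets(spacer, p2$genome, 2), on_target))
  # monotone: adding hits can only flip true -> false
  expect_true(is_likely_specific(hits[0, ], on_target))
})

test_that("species reactivity requires a perfect NGG match on either strand", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(2000, 12))
  stopifnot(!species_reactive(spacer, genome))
  exact_plus <- plant_site(genome, "chr", 50, spacer, 0, pam = "TGG", seed = 1)
  expect_true(species_reactive(spacer, exact_plus$genome))
  exact_minus <- plant_site(genome, "chr", 50, spacer, 0, pam = "GGG",
                            strand = "-", seed = 2)
  expect_true(species_reactive(spacer, exact_minus$genome))
  near <- plant_site(genome, "chr", 50, spacer, 1, pam = "TGG", seed = 3)
  expect_false(species_reactive(spacer, near$genome))
})

test_that("CFD scoring multiplies per-mismatch and PAM penalties", {
  tables <- load_cfd_tables()
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(3000, 11))
  g0 <- plant_site(genome, "chr", 100, spacer, 0, pam = "CGG", seed = 1)
  g1 <- plant_site(g0$genome, "chr", 500, spacer, 1, pam = "AGG", seed = 2)
  g2 <- plant_site(g1$genome, "chr", 900, spacer, 2, pam = "TGG", seed = 3)
  hits <- scan_offtargets(spacer, g2$genome, 2)
  scores <- cfd_score(hits, tables)
  # perfect NGG match scores exactly 1 (empty product x GG penalty 1)
  expect_identical(scores[hits$mismatch_count == 0], 1)
  # single mismatch: the table entry for that triple times the PAM penalty
  h1 <- hits[hits$mismatch_count == 1, ]
  det <- h1$mismatches[[1]]
  entry <- tables$mismatch$penalty[
    tables$mismatch$position == det$position &
      tables$mismatch$guide_base == det$guide_base &
      tables$mismatch$site_base == det$site_base]
  pamp <- tables$pam$penalty[tables$pam$dinucleotide ==
                               substr(h1$pam_observed, 2, 3)]
  expect_equal(scores[hits$mismatch_count == 1], entry * pamp)
  # two mismatches: product of the two entries
  h2 <- hits[hits$mismatch_count == 2, ]
  det2 <- h2$mismatches[[1]]
  entries <- vapply(1:2, function(k) tables$mismatch$penalty[
    tables$mismatch$position == det2$position[k] &
      tables$mismatch$guide_base == det2$guide_base[k] &
      tables$mismatch$site_base == det2$site_base[k]], numeric(1))
  pamp2 <- tables$pam$penalty[tables$pam$dinucleotide ==
                                substr(h2$pam_observed, 2, 3)]
  expect_equal(scores[hits$mismatch_count == 2], prod(entries) * pamp2)
  # scores never exceed the perfect-match score
  expect_true(all(scores <= 1))
  # a table missing the needed triple errors naming the lookup
  broken <- tables
  broken$mismatch <- broken$mismatch[-seq_len(nrow(broken$mismatch)), ]
  expect_error(cfd_score(h1, broken), "position",
               class = "guidescreen_parameter_error")
})

test_that("MIT scoring matches the closed form and aggregates sensibly", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(3000, 11))
  g0 <- plant_site(genome, "chr", 100, spacer, 0, pam = "CGG", seed = 1)
  g1 <- plant_site(g0$genome, "chr", 500, spacer, 1, pam = "AGG", seed = 2)
  hits01 <- scan_offtargets(spacer, g1$genome, 2)
  # no off-target hits -> aggregate 100
  expect_identical(mit_scores(hits01[hits01$mismatch_count == 0, ])$aggregate, 100)
  # single mismatch with all-zero weights: per-hit = 100 x 1 x 1 x 1
  zero_w <- rep(0, 20)
  one_mm <- hits01[hits01$mismatch_count == 1, ]
  expect_equal(mit_scores(one_mm, zero_w)$per_hit, 100)
  # with the shipped weights the per-hit penalty applies at that position
  w <- load_mit_weights()
  p <- one_mm$mismatches[[1]]$position
  expect_equal(mit_scores(one_mm, w)$per_hit, 100 * (1 - w[p]))
  # two-mismatch closed form: weights, spacing penalty, 1/m^2
  g2 <- plant_site(g1$genome, "chr", 900, spacer, 2, pam = "TGG", seed = 3)
  hits <- scan_offtargets(spacer, g2$genome, 2)
  two_mm <- hits[hits$mismatch_count == 2, ]
  pos <- two_mm$mismatches[[1]]$position
  dbar <- mean(dist(pos))
  want <- 100 * prod(1 - w[pos]) * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / 4)
  expect_equal(mit_scores(two_mm, w)$per_hit, want)
  # aggregate strictly decreases as off-target hits are appended
  a1 <- mit_scores(hits01, w)$aggregate
  a2 <- mit_scores(hits, w)$aggregate
  expect_lt(a2, a1)
  expect_lt(a1, 100)
})

test_that("genomic context classification uses half-open-style 1-nt overlap", {
  hits <- tibble::tibble(contig = "c", start = c(10L, 200L, 900L, 478L),
                         end = c(32L, 222L, 922L, 500L))
  exons <- tibble::tibble(contig = "c", start = c(1L, 500L), end = c(50L, 600L))
  genes <- tibble::tibble(contig = "c", start = 1L, end = 700L)
  expect_identical(classify_context(hits, exons, genes),
                   c("exonic", "intronic", "intergenic", "exonic"))
})

test_that("paralog check restricts relaxed-threshold hits to paralog CDS", {
  spacer <- "ACGTACGTACGTACGTACGT"
  genome <- c(chr = random_seq(4000, 13))
  paralog_cds <- tibble::tibble(contig = "chr", start = 1000L, end = 1500L)
  # 5 mismatches even inside the region: above threshold, no hit
  p5 <- plant_site(genome, "chr", 1100, spacer, 5, pam = "AGG", seed = 1)
  expect_identical(nrow(paralog_check(spacer, p5$genome, paralog_cds)), 0L)
  # 4 mismatches inside the region: exactly one hit
  p4 <- plant_site(genome, "chr", 1100, spacer, 4, pam = "AGG", seed = 2)
  expect_identical(nrow(paralog_check(spacer, p4$genome, paralog_cds)), 1L)
  # 4 mismatches outside the region: excluded
  p4out <- plant_site(genome, "chr", 3000, spacer, 4, pam = "AGG", seed = 3)
  expect_identical(nrow(paralog_check(spacer, p4out$genome, paralog_cds)), 0L)
})

test_that("bulged search is rejected as unsupported", {
  expect_error(scan_offtargets("ACGTACGTACGTACGTACGT", c(c = "ACGT"), dna_bulge = 1),
               class = "guidescreen_parameter_error")
})

test_that("specificity report ties the pieces together per guide", {
  fx <- toy_fixture()
  span <- range(unlist(fx$model$isoforms$long))
  sites <- enumerate_protospacers(fx$genome, "toy_chr", span[1] + 1, span[2])
  guides <- sites[c(5, 50), ]
  species <- list(other = c(chr = paste0(guides$spacer[1], "TGG",
                                         random_seq(200, 21))))
  rep <- specificity_report(guides, fx$genome, species = species)
  expect_true(all(c("likely_specific", "mit_specificity", "cfd_spec",
                    "reactive_other") %in% names(rep)))
  expect_identical(rep$reactive_other, c(TRUE, FALSE))
  expect_true(all(rep$mit_specificity <= 100 & rep$mit_specificity > 0))
})
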