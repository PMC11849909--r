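# one shared assay built from the toy gene for all quantification tests
local_assay <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- toy_fixture()
      span <- range(unlist(fx$model$isoforms$long))
      sites <- enumerate_protospacers(fx$genome, "toy_chr", span[1] + 1, span[2])
      g <- sites[100, ]
      cache <<- amplicon_assay(guide_amplicon(fx$genome, g), g$spacer,
                               guide_id = "g100")
    }
    cache
  }
})

test_that("assay construction locates the guide and fixes the window", {
  spacer <- "GATTACAGATTACAGATTAC"
  amp <- paste0(random_seq(100, 31), spacer, "TGG", random_seq(100, 32))
  a <- amplicon_assay(amp, spacer)
  # cut junction 3 nt 5' of the PAM: after amplicon position 100 + 17
  expect_identical(a$cut_junction, 117L)
  expect_identical(a$window, c(117L, 117L))
  # same guide placed on the minus strand of the amplicon
  a2 <- amplicon_assay(revcomp(amp), spacer)
  expect_identical(a2$guide_strand, "-")
  expect_identical(a2$cut_junction, nchar(amp) - 117L)
  # absent or duplicated protospacers are rejected
  expect_error(amplicon_assay(random_seq(100, 33), spacer),
               class = "guidescreen_parameter_error")
  expect_error(amplicon_assay(paste0(amp, amp), spacer),
               class = "guidescreen_parameter_error")
})

test_that("alignment reproduces identity, gaps and the DP score", {
  a <- local_assay()
  amp <- a$amplicon
  # a perfect read: identity 100, no gaps
  aln <- align_reads(a, amp)
  expect_equal(aln$identity, 100)
  expect_identical(nrow(aln$deletions[[1]]) + nrow(aln$insertions[[1]]), 0L)
  # one 2-nt deletion: a single gap of width 2, score equal to the
  # independent dynamic-programming oracle
  read <- paste0(substr(amp, 1, 120), substr(amp, 123, nchar(amp)))
  aln2 <- align_reads(a, read)
  expect_identical(nrow(aln2$deletions[[1]]), 1L)
  expect_identical(aln2$deletions[[1]]$width, 2L)
  expect_equal(aln2$score, oracle_nw_score(read, amp))
  # a reverse-complement read gives identical calls
  aln3 <- align_reads(a, revcomp(read))
  expect_identical(aln3$orientation, "-")
  expect_equal(aln3$identity, aln2$identity)
  expect_identical(as.data.frame(aln3$deletions[[1]]),
                   as.data.frame(aln2$deletions[[1]]))
})

test_that("edit calling implements the window, homology and frame rules", {
  a <- local_assay()
  amp <- a$amplicon
  j <- a$cut_junction
  # perfect read: unmodified, net 0
  c0 <- call_edits(a, amp)
  expect_identical(c0$status, "unmodified")
  expect_identical(c0$net_indel, 0L)
  # 1-nt insertion at the cut: modified, net +1, frameshift
  r_ins <- paste0(substr(amp, 1, j), "C", substr(amp, j + 1, nchar(amp)))
  c1 <- call_edits(a, r_ins)
  expect_identical(c1$status, "modified")
  expect_identical(c1$net_indel, 1L)
  expect_true(c1$frameshift)
  # 3-nt deletion spanning the cut: modified, net -3, in frame
  r_del <- paste0(substr(amp, 1, j - 2), substr(amp, j + 2, nchar(amp)))
  c3 <- call_edits(a, r_del)
  expect_identical(c3$status, "modified")
  expect_identical(c3$net_indel, -3L)
  expect_false(c3$frameshift)
  # substitutions alone leave a read unmodified
  ch <- strsplit(amp, "")[[1]]
  ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
  expect_identical(call_edits(a, paste(ch, collapse = ""))$status, "unmodified")
  # an indel far from the window does not modify the call
  r_far <- paste0(substr(amp, 1, 10), substr(amp, 12, nchar(amp)))
  expect_identical(call_edits(a, r_far)$status, "unmodified")
  # a read sharing almost nothing with the amplicon is discarded: a short
  # random fragment forces most alignment columns to be gaps
  cb <- call_edits(a, random_seq(80, 44))
  expect_identical(cb$status, "discarded_low_homology")
})

test_that("quantification handles degenerate inputs explicitly", {
  a <- local_assay()
  # all-unedited reads -> (0, 0)
  q0 <- quantify_edits(a, rep(a$amplicon, 5))
  expect_identical(q0$indel_rate, 0)
  expect_identical(q0$frameshift_rate, 0)
  # all reads below homology -> explicit no-data result
  qb <- quantify_edits(a, replicate(3, random_seq(300, 45)))
  expect_identical(qb$n_used, 0L)
  expect_true(is.na(qb$indel_rate) && is.na(qb$frameshift_rate))
})

test_that("programmed spectra are recovered within 3 binomial SDs at n = 10000", {
  a <- local_assay()
  spectrum <- data.frame(net_indel = c(0L, 1L, -3L), prob = c(0.5, 0.3, 0.2))
  sim <- sim_reads(a, spectrum, n = 10000L, seed = 8)
  q <- quantify_edits(a, sim$reads)
  sd_indel <- sqrt(0.5 * 0.5 / 10000)
  sd_fs <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(q$indel_rate - sim$truth$indel_rate), 3 * sd_indel)
  expect_lt(abs(q$frameshift_rate - sim$truth$frameshift_rate), 3 * sd_fs)
  # frameshift never exceeds indel
  expect_lte(q$frameshift_rate, q$indel_rate)
})

test_that("quantification is invariant to read strand and amplicon padding", {
  a <- local_assay()
  spectrum <- data.frame(net_indel = c(0L, 2L, -2L, -6L), prob = c(0.4, 0.2, 0.2, 0.2))
  sim <- sim_reads(a, spectrum, n = 300L, seed = 9)
  q1 <- quantify_edits(a, sim$reads)
  q2 <- quantify_edits(a, revcomp(sim$reads))
  expect_identical(q1$indel_rate, q2$indel_rate)
  expect_identical(q1$frameshift_rate, q2$frameshift_rate)
  # pad the amplicon symmetrically; pad the reads the same way
  pad <- random_seq(25, 46)
  pad2 <- random_seq(25, 47)
  a_pad <- amplicon_assay(paste0(pad, a$amplicon, pad2), a$spacer)
  # bring each read to amplicon orientation before padding its ends
  oriented <- ifelse(align_reads(a, sim$reads)$orientation == "-",
                     revcomp(sim$reads), sim$reads)
  q3 <- quantify_edits(a_pad, paste0(pad, oriented, pad2))
  expect_identical(q1$indel_rate, q3$indel_rate)
  expect_identical(q1$frameshift_rate, q3$frameshift_rate)
})

test_that("programmed fractions are recovered without bias across seeds", {
  a <- local_assay()
  spectrum <- data.frame(net_indel = c(0L, 1L, -1L, -3L, 4L),
                         prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
  n <- 10000L
  err_i <- err_f <- numeric(20)
  for (s in 1:20) {
    sim <- sim_reads(a, spectrum, n = n, seed = 100 + s)
    q <- quantify_edits(a, sim$reads)
    err_i[s] <- q$indel_rate - sim$truth$indel_rate
    err_f[s] <- q$frameshift_rate - sim$truth$frameshift_rate
    expect_lte(q$frameshift_rate, q$indel_rate)
  }
  expect_lt(abs(mean(err_i)), 0.005)
  expect_lt(abs(mean(err_f)), 0.005)
})

test_that("screen summaries compute means, SDs and a deterministic rank", {
  res <- tibble::tibble(
    guide_id = rep(c("g1", "g2", "g3"), each = 3),
    spacer = rep(c("CCC", "AAA", "BBB"), each = 3),
    indel_rate = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.5, 0.6, 0.7),
    frameshift_rate = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.4, 0.5, 0.6)
  )
  s <- summarize_screen(res, guide_id)
  expect_equal(s$mean_frameshift[s$guide_id == "g1"], 0.2)
  expect_equal(s$sd_frameshift[s$guide_id == "g1"], 0.1)
  # g2 and g3 tie on the mean; the spacer lexicographic order breaks it
  expect_identical(s$guide_id[s$rank == 1L], "g2")  # spacer AAA < BBB
  expect_identical(s$guide_id[s$rank == 2L], "g3")
  # single replicate: SD absent
  s1 <- summarize_screen(res[c(1, 4, 7), ], guide_id)
  expect_true(all(is.na(s1$sd_frameshift)))
  # rank stability: adding a guide preserves relative order of the others
  res4 <- dplyr::bind_rows(res, tibble::tibble(
    guide_id = "g4", spacer = "DDD", indel_rate = 0.55, frameshift_rate = 0.45))
  s4 <- summarize_screen(res4, guide_id)
  old <- s$guide_id[order(s$rank)]
  new <- s4$guide_id[order(s4$rank)]
  expect_identical(new[new != "g4"], old)
})

test_that("condition comparisons fit OLS and recover known slopes", {
  d <- tibble::tibble(x = seq(0.05, 0.6, length.out = 22))
  # identity (suppress lm's perfect-fit chatter)
  fit <- suppressWarnings(compare_conditions(dplyr::mutate(d, y = x), x, y))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  # perfect negative relation
  fit2 <- suppressWarnings(compare_conditions(dplyr::mutate(d, y = -x + 1), x, y))
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$r_squared, 1)
  # noisy slope recovery within 2 standard errors
  set.seed(10)
  fit3 <- compare_conditions(
    dplyr::mutate(d, y = 0.8 * x + stats::rnorm(22, 0, 0.01)), x, y)
  se <- tidy(fit3)$std.error[2]
  expect_lt(abs(fit3$slope - 0.8), 2 * se)
  # tidy/glance expose the fit like any model object
  expect_identical(nrow(tidy(fit3)), 2L)
  expect_identical(glance(fit3)$n, 22L)
  expect_error(compare_conditions(d[1:2, ] |> dplyr::mutate(y = x), x, y),
               class = "guidescreen_parameter_error")
})

test_that("frameshift-deviation flagging is an exact binomial test against 2/3", {
  out <- flag_frameshift_deviation(c(1333L, 800L, 5L), c(2000L, 2000L, 10L))
  # at expectation: not flagged
  expect_false(out$flagged[1])
  # strong in-frame skew in a large sample: flagged
  expect_true(out$flagged[2])
  expect_equal(out$p_value[2],
               stats::binom.test(800, 2000, 2 / 3)$p.value)
  # the same skew in an underpowered sample (5 of 10, like 1000 of 2000,
  # which does flag): not flagged
  expect_false(out$flagged[3])
  expect_true(flag_frameshift_deviation(1000L, 2000L)$flagged)
})

test_that("candidate selection is a deterministic filtered top-k", {
  set.seed(12)
  s <- tibble::tibble(
    guide_id = sprintf("g%02d", 1:30),
    spacer = sprintf("S%02d", 1:30),
    mean_frameshift = stats::runif(30),
    upstream_of_inframe_cug = rep(c(TRUE, FALSE), c(4, 26)),
    likely_specific = TRUE
  )
  top22 <- select_candidates(s, 22, !upstream_of_inframe_cug)
  expect_identical(nrow(top22), 22L)
  expect_true(!any(top22$upstream_of_inframe_cug))
  expect_identical(top22$mean_frameshift,
                   sort(s$mean_frameshift[!s$upstream_of_inframe_cug],
                        decreasing = TRUE)[1:22])
  expect_identical(nrow(select_candidates(s, 0, !upstream_of_inframe_cug)), 0L)
  expect_warning(got <- select_candidates(s, 40), "40")
  expect_identical(nrow(got), 30L)
})
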