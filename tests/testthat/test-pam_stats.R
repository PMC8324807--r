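tpl <- default_template()
no_noise <- error_model(substitution_rate = 0, n_rate = 0, adapter_rate = 0)

mk_tally <- function(df) {
  df$n_total <- df$n_TGG + df$n_TGA + df$n_TAG + df$n_TAA + df$n_other
  structure(df[, c("pam", "n_total", "n_TGG", "n_TGA", "n_TAG", "n_TAA",
                   "n_other")],
            class = c("pam_tally", "data.frame"))
}

test_that("editing efficiency is the stop-codon read fraction", {
  t1 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 20, n_TGA = 50,
                            n_TAG = 10, n_TAA = 20, n_other = 0))
  expect_equal(be_efficiency(t1), 0.8)
  t2 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 50, n_TGA = 0,
                            n_TAG = 0, n_TAA = 0, n_other = 0))
  expect_equal(be_efficiency(t2), 0)
  # OTHER dilutes the denominator but never the numerator
  t3 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 40, n_TGA = 40,
                            n_TAG = 0, n_TAA = 0, n_other = 20))
  expect_equal(be_efficiency(t3), 0.4)
  t0 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 0, n_TGA = 0,
                            n_TAG = 0, n_TAA = 0, n_other = 0))
  expect_true(is.na(be_efficiency(t0)))
})

test_that("efficiency estimates recover the generator's editing rate", {
  rs <- generate_library_reads(c(GGGA = 1), 0.30, tpl, 1000, no_noise,
                               seed = 71)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  est <- be_efficiency(tally)
  expect_lt(abs(est - 0.30), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("mutation pattern normalizes the three stop outcomes", {
  t1 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 0, n_TGA = 50,
                            n_TAG = 20, n_TAA = 30, n_other = 0))
  expect_equal(mutation_pattern(t1), c(TGA = 0.5, TAA = 0.3, TAG = 0.2))
  t2 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 5, n_TGA = 1,
                            n_TAG = 0, n_TAA = 0, n_other = 0))
  expect_equal(mutation_pattern(t2), c(TGA = 1, TAA = 0, TAG = 0))
  t0 <- mk_tally(data.frame(pam = "AGGA", n_TGG = 5, n_TGA = 0,
                            n_TAG = 0, n_TAA = 0, n_other = 0))
  expect_warning(mp <- mutation_pattern(t0), "undefined")
  expect_true(all(is.na(mp)))
})

test_that("generator edit-type split is recovered within multinomial error", {
  rs <- generate_library_reads(c(GGGA = 1), 1.0, tpl, 10000, no_noise,
                               seed = 73)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  mp <- mutation_pattern(process_fastq(fq, tpl))
  p <- c(TGA = 0.5, TAA = 0.3, TAG = 0.2)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(mp - p) < 3 * se))
})

test_that("enrichment factor follows its printed definition", {
  initial <- mk_tally(data.frame(
    pam = c("AGGA", "TTTT"),
    n_TGG = c(10, 990), n_TGA = c(0, 0), n_TAG = c(0, 0), n_TAA = c(0, 0),
    n_other = c(0, 0)))
  enriched <- mk_tally(data.frame(
    pam = c("AGGA", "TTTT"),
    n_TGG = c(10, 910), n_TGA = c(80, 0), n_TAG = c(0, 0), n_TAA = c(0, 0),
    n_other = c(0, 0)))
  ef <- enrichment_factor(initial, enriched)
  expect_equal(unname(ef["AGGA"]), 0.08 / 0.01)  # = 8
  # identity libraries with full editing cancel to EF = 1
  full <- mk_tally(data.frame(
    pam = c("AGGA", "TTTT"), n_TGG = c(0, 0), n_TGA = c(10, 990),
    n_TAG = c(0, 0), n_TAA = c(0, 0), n_other = c(0, 0)))
  init_counts <- mk_tally(data.frame(
    pam = c("AGGA", "TTTT"), n_TGG = c(10, 990), n_TGA = c(0, 0),
    n_TAG = c(0, 0), n_TAA = c(0, 0), n_other = c(0, 0)))
  ef1 <- enrichment_factor(init_counts, full)
  expect_equal(unname(ef1), c(1, 1))
  # PAM absent from the initial library: undefined, flagged as NA
  enr2 <- mk_tally(data.frame(pam = "CCCC", n_TGG = 0, n_TGA = 5,
                              n_TAG = 0, n_TAA = 0, n_other = 0))
  ef2 <- enrichment_factor(init_counts, enr2)
  expect_true(is.na(ef2["CCCC"]))
  # all-reads numerator variant
  ef_all <- enrichment_factor(initial, enriched, numerator = "all")
  expect_equal(unname(ef_all["AGGA"]), 0.09 / 0.01)
})

test_that("an invalid PAM drifts to near-zero enrichment in a simulated screen", {
  params <- screen_params(edit_prob = c(GGGA = 0.1, TTTT = 0),
                          background_escape = 0, unedited_survival = 0.02,
                          rounds = 2, mode = "deterministic")
  init <- init_population(c(GGGA = 1, TTTT = 1))
  traj <- run_screen(init, params)
  rs_i <- couple_to_reads(traj$populations[[1]], tpl, 20000, no_noise,
                          seed = 81)
  rs_e <- couple_to_reads(traj$populations[[3]], tpl, 20000, no_noise,
                          seed = 82)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs_i, f1)
  write_read_set(rs_e, f2)
  ef <- enrichment_factor(process_fastq(f1, tpl), process_fastq(f2, tpl))
  expect_lt(ef[["TTTT"]], 0.05)
  expect_gt(ef[["GGGA"]], 1)
})

test_that("functional and enriched calls use strict thresholds", {
  st <- data.frame(efficiency = c(0.011, 0.01, NA),
                   enrichment_factor = c(5, 1, NA))
  expect_identical(call_functional(st), c(TRUE, FALSE, FALSE))
  expect_identical(call_enriched(st), c(TRUE, FALSE, FALSE))
})

test_that("the functional call recovers exactly the truly active PAMs", {
  pams <- enumerate_pams(4)
  active <- pams[seq_len(40)]
  ef <- stats::setNames(rep(0, 256), pams)
  ef[active] <- 0.2
  rs <- generate_library_reads(uniform_256(), ef, tpl, 50000, no_noise,
                               seed = 83)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  st <- data.frame(pam = tally$pam, efficiency = be_efficiency(tally))
  called <- st$pam[call_functional(st)]
  expect_identical(sort(called), sort(active))
})

test_that("fold enrichment reproduces the mixing-experiment arithmetic", {
  expect_equal(fold_enrichment(0.073, 0.676), 9.26, tolerance = 1e-3)
  expect_identical(round_fold(fold_enrichment(0.073, 0.676)), 9)
  expect_equal(fold_enrichment(0.010, 0.552), 55.2)
  expect_identical(round_fold(fold_enrichment(0.010, 0.552)), 55)
  expect_equal(fold_enrichment(0.4, 0.4), 1)
  expect_error(fold_enrichment(0, 0.5), "0, 1")
  # round-half-away-from-zero convention
  expect_identical(round_fold(c(2.5, 3.5, -2.5)), c(3, 4, -3))
})

test_that("uniformity check is exact on constructed tallies", {
  pams <- enumerate_pams(4)
  flat <- mk_tally(data.frame(pam = pams, n_TGG = 100, n_TGA = 0,
                              n_TAG = 0, n_TAA = 0, n_other = 0))
  u <- uniformity_check(flat)
  expect_equal(u$chi2, 0)
  expect_equal(u$cv, 0)
  expect_equal(u$p_value, 1)
  # one PAM absent of 256 at n = 25600: that cell alone contributes
  # (0 - 100)^2 / 100 = 100
  miss <- flat[-1, ]
  u2 <- uniformity_check(miss, k = 4)
  # remaining cells: expected shifts from 100 to 25500/256
  e <- 25500 / 256
  expect_equal(u2$chi2, e + 255 * (100 - e)^2 / e, tolerance = 1e-9)
  expect_equal(u2$min_freq, 0)
})

test_that("uniformity p-values are calibrated under the null", {
  pams <- enumerate_pams(2)
  pvals <- vapply(1:60, function(s) {
    set.seed(s)
    draw <- as.integer(stats::rmultinom(1, 3200, rep(1 / 16, 16)))
    tly <- mk_tally(data.frame(pam = pams, n_TGG = draw, n_TGA = 0,
                               n_TAG = 0, n_TAA = 0, n_other = 0))
    uniformity_check(tly, k = 2)$p_value
  }, numeric(1))
  # roughly uniform: Kolmogorov-Smirnov should not reject wildly
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("replicate merging averages statistics and intersects calls", {
  t1 <- structure(data.frame(pam = c("AGGA", "CGGA"),
                             efficiency = c(0.8, 0.02),
                             enrichment_factor = c(4, 2),
                             functional = c(TRUE, TRUE),
                             enriched = c(TRUE, TRUE)),
                  class = c("pam_stats", "data.frame"))
  t2 <- t1
  t2$efficiency <- c(0.6, 0.005)
  t2$functional <- c(TRUE, FALSE)
  merged <- merge_replicates(list(t1, t2))
  expect_equal(merged$efficiency, c(0.7, 0.0125))
  expect_identical(merged$functional, c(TRUE, FALSE))
  expect_equal(merged$efficiency_rep2, c(0.6, 0.005))
  # identical tables: mean equals each replicate
  same <- merge_replicates(list(t1, t1))
  expect_equal(same$efficiency, t1$efficiency)
  t3 <- t1
  t3$pam <- c("AGGA", "TTTT")
  expect_error(merge_replicates(list(t1, t3)), "mismatched")
})

test_that("stats tables survive a TSV round trip", {
  init <- mk_tally(data.frame(pam = c("AGGA", "TTTT"), n_TGG = c(100, 100),
                              n_TGA = c(0, 0), n_TAG = c(0, 0),
                              n_TAA = c(0, 0), n_other = c(0, 0)))
  enr <- mk_tally(data.frame(pam = c("AGGA", "TTTT"), n_TGG = c(20, 150),
                             n_TGA = c(25, 0), n_TAG = c(2, 0),
                             n_TAA = c(3, 0), n_other = c(0, 0)))
  st <- pam_stats(init, enr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pam_stats(st, path)
  back <- read_pam_stats(path)
  expect_equal(back$efficiency, st$efficiency)
  expect_identical(back$functional, st$functional)
})
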