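tpl <- default_template()
no_noise <- error_model(substitution_rate = 0, n_rate = 0, adapter_rate = 0)
ADAPTER <- error_model()$adapter_seq

make_qreads <- function(seqs, phred = 35L) {
  q <- vapply(nchar(seqs), function(n)
    strrep(rawToChar(as.raw(phred + 33L)), n), character(1))
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
  names(r) <- sprintf("r%03d", seq_along(seqs))
  r
}

resolved_params <- function(...) {
  p <- cleaning_params(...)
  if (is.na(p$min_length)) p$min_length <- tpl$codon_slot[2]
  p
}

test_that("clean reads pass through untouched; damaged reads are rejected by reason", {
  amp <- synthesize_amplicon(tpl, "AGGT", "UNEDITED_TGG")
  n30 <- paste0(strrep("N", 46), substr(amp, 47, 152))  # 30% N
  short <- substr(amp, 1, 30)
  reads <- make_qreads(c(amp, n30, short))
  cl <- clean_reads(reads, resolved_params())
  expect_identical(cl$keep, c(TRUE, FALSE, FALSE))
  expect_identical(cl$reason, c(NA, "too_many_N", "too_short"))
  expect_identical(as.character(cl$reads[[1]]), amp)
})

test_that("low mean quality rejects a read", {
  amp <- synthesize_amplicon(tpl, "AGGT", "UNEDITED_TGG")
  reads <- make_qreads(amp, phred = 12L)
  cl <- clean_reads(reads, resolved_params())
  expect_identical(cl$reason, "low_quality")
})

test_that("adapter tails are trimmed where a brute-force suffix search finds them", {
  amp <- synthesize_amplicon(tpl, "CATG", "EDITED_TGA")
  with_tail <- paste0(amp, ADAPTER)
  partial <- paste0(amp, substr(ADAPTER, 1, 12))
  too_short_tail <- paste0(amp, substr(ADAPTER, 1, 8))  # below seed length
  reads <- make_qreads(c(with_tail, partial, too_short_tail))
  cl <- clean_reads(reads, resolved_params())
  expect_true(all(cl$keep))
  # brute-force oracle: first position whose following bases start the adapter
  oracle_cut <- function(s) {
    seed <- substr(ADAPTER, 1, 10)
    for (i in seq_len(nchar(s) - 9)) {
      win <- substr(s, i, i + 9)
      if (sum(strsplit(win, "")[[1]] != strsplit(seed, "")[[1]]) <= 1)
        return(i - 1L)
    }
    nchar(s)
  }
  expect_identical(Biostrings::width(cl$reads),
                   vapply(c(with_tail, partial, too_short_tail), oracle_cut,
                          integer(1), USE.NAMES = FALSE))
  expect_identical(Biostrings::width(cl$reads)[1], nchar(amp))
})

test_that("a read that is all adapter is rejected as adapter_only", {
  reads <- make_qreads(paste0(ADAPTER, ADAPTER))
  cl <- clean_reads(reads, resolved_params())
  expect_identical(cl$reason, "adapter_only")
})

test_that("extraction recovers PAM and state on both strands with zero mismatches", {
  amp <- synthesize_amplicon(tpl, "GTGC", "EDITED_TAA")
  reads <- make_qreads(c(amp, revcomp(amp)))
  ex <- extract_observations(reads, tpl)
  expect_identical(nrow(ex$obs), 2L)
  expect_identical(ex$obs$pam, c("GTGC", "GTGC"))
  expect_identical(ex$obs$state, c("EDITED_TAA", "EDITED_TAA"))
  expect_identical(ex$obs$strand, c("fwd", "rev"))
  expect_identical(ex$obs$anchor_mismatches, c(0L, 0L))
})

test_that("anchors degraded beyond the tolerance reject the read", {
  amp <- synthesize_amplicon(tpl, "GTGC", "UNEDITED_TGG")
  broken <- amp
  for (i in c(2, 7, 13)) {  # three substitutions inside anchor5
    cur <- substr(broken, i, i)
    substr(broken, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  ex <- extract_observations(make_qreads(broken), tpl, max_anchor_mm = 2)
  expect_identical(ex$reason, "no_anchor")
  # the exhaustive Hamming-scan oracle agrees
  orc <- oracle_extract(broken, tpl, max_anchor_mm = 2)
  expect_false(orc$accepted)
  # two substitutions stay within tolerance, for both paths
  two_mm <- amp
  for (i in c(2, 7)) {
    cur <- substr(two_mm, i, i)
    substr(two_mm, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  ex2 <- extract_observations(make_qreads(two_mm), tpl, max_anchor_mm = 2)
  expect_identical(ex2$obs$pam, "GTGC")
  expect_identical(ex2$obs$anchor_mismatches, 2L)
  expect_true(oracle_extract(two_mm, tpl, 2)$accepted)
})

test_that("a PAM containing N is rejected, never imputed", {
  amp <- synthesize_amplicon(tpl, "GTGC", "UNEDITED_TGG")
  substr(amp, tpl$pam_slot[1] + 2, tpl$pam_slot[1] + 2) <- "N"
  ex <- extract_observations(make_qreads(amp), tpl)
  expect_identical(ex$reason, "ambiguous_pam")
})

test_that("processing an empty FASTQ yields a zero tally", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  tally <- process_fastq(fq, tpl)
  expect_identical(nrow(tally), 0L)
  expect_identical(tally_qc(tally)$reads_in, 0L)
})

test_that("round trip without noise reproduces the truth table exactly", {
  rs <- generate_library_reads(uniform_256(), 0.3, tpl, 20000, no_noise,
                               seed = 21)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  qc <- tally_qc(tally)
  expect_identical(qc$reads_in, 20000L)
  expect_identical(sum(unlist(qc$rejected)), 0L)
  expect_identical(sum(tally$n_total), 20000L)
  # per-PAM, per-state equality with the generator's truth
  cols <- c(UNEDITED_TGG = "n_TGG", EDITED_TGA = "n_TGA",
            EDITED_TAG = "n_TAG", EDITED_TAA = "n_TAA")
  truth <- rs$truth
  for (r in seq_len(nrow(truth))) {
    got <- tally[tally$pam == truth$pam[r], cols[[truth$state[r]]]]
    expect_identical(as.integer(got), truth$count[r])
  }
})

test_that("uniform unedited library recovers every PAM near its expected depth", {
  rs <- generate_library_reads(uniform_256(), 0, tpl, 25600, no_noise,
                               seed = 31)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  expect_identical(nrow(tally), 256L)
  expect_true(all(abs(tally$n_TGG - 100) < 5 * sqrt(100)))
  expect_true(all(tally$n_TGA + tally$n_TAG + tally$n_TAA + tally$n_other
                  == 0))
})

test_that("QC accounting identity holds on noisy input", {
  em <- error_model(substitution_rate = 0.02, n_rate = 0.01,
                    adapter_rate = 0.2)
  rs <- generate_library_reads(uniform_256(), 0.3, tpl, 4000, em, seed = 41)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  qc <- tally_qc(tally)
  clean_rej <- sum(qc$rejected[c("adapter_only", "too_many_N",
                                 "low_quality", "too_short")])
  extract_rej <- sum(qc$rejected[c("no_anchor", "ambiguous",
                                   "ambiguous_pam")])
  expect_identical(qc$reads_in, qc$reads_cleaned_out + clean_rej)
  expect_identical(qc$reads_cleaned_out,
                   qc$reads_classified + extract_rej)
  expect_identical(sum(tally$n_total), qc$reads_classified)
})

test_that("tallies are invariant under reverse complementing every read", {
  em <- error_model(substitution_rate = 0.005, n_rate = 0.001,
                    adapter_rate = 0)
  rs <- generate_library_reads(uniform_256(), 0.3, tpl, 3000, em, seed = 51)
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq1)
  flipped <- Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rs$reads))
  qual <- as.character(Biostrings::quality(rs$reads))
  qual <- vapply(strsplit(qual, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  out <- Biostrings::QualityScaledDNAStringSet(
    flipped, Biostrings::PhredQuality(qual))
  names(out) <- names(rs$reads)
  Biostrings::writeQualityScaledXStringSet(out, fq2)
  t1 <- tally_counts(process_fastq(fq1, tpl))
  t2 <- tally_counts(process_fastq(fq2, tpl))
  expect_identical(t1, t2)
})

test_that("tally TSV round trip preserves counts and QC", {
  rs <- generate_library_reads(c(ACGG = 3, TTTT = 1), 0.4, tpl, 500,
                               no_noise, seed = 61)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_read_set(rs, fq)
  tally <- process_fastq(fq, tpl)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tally(tally, path)
  back <- read_tally(path)
  expect_equal(tally_counts(back), tally_counts(tally))
  expect_equal(tally_qc(back)$reads_in, 500)
})

test_that("missing FASTQ paths raise an I/O error naming the file", {
  expect_error(process_fastq("/no/such/file.fastq", tpl),
               "no/such/file.fastq")
})
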