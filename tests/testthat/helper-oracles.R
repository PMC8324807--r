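# Independent reference implementations used as test oracles. These stay
# deliberately separate from the package's code paths: plain substring
# arithmetic instead of Biostrings matching, and closed-form recursions
# instead of the step-by-step simulator.

# complement lookup kept local to the oracle
.orc_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    v <- strsplit(s, "")[[1]]
    paste(rev(unname(.orc_comp[v])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive sliding-window Hamming search: for every read, every offset on
# both orientations is scored (anchor5 mismatches + constant-check
# mismatches); placements within the tolerance compete on total mismatches
# and only a unique best placement yields an observation. Vectorized over
# reads per offset, but algorithmically independent of the package's
# matcher.
oracle_extract <- function(read_seqs, template, max_anchor_mm = 2L) {
  a5 <- template$anchor5
  a5v <- strsplit(a5, "")[[1]]
  check_len <- template$codon_slot[1] - template$pam_slot[2]
  chk <- substr(template$anchor3, 1L, check_len)
  chkv <- strsplit(chk, "")[[1]]
  span <- template$codon_slot[2]
  pam_off <- template$pam_slot[1]
  plen <- template$pam_length
  codon_off <- template$codon_slot[1]

  n <- length(read_seqs)
  strands <- list(fwd = read_seqs, rev = oracle_revcomp(read_seqs))
  # per-read best bookkeeping
  best_mm <- rep(Inf, n)
  best_cnt <- integer(n)          # how many placements achieve best_mm
  best_pam <- best_codon <- best_strand <- rep(NA_character_, n)

  mm_at <- function(s, at, patv) {
    m <- integer(length(s))
    for (j in seq_along(patv))
      m <- m + (substr(s, at + j - 1L, at + j - 1L) != patv[j])
    m
  }
  for (strand in c("fwd", "rev")) {
    s <- strands[[strand]]
    L <- nchar(s)
    for (off in seq_len(max(L) - span + 1L)) {
      fits <- off + span - 1L <= L
      if (!any(fits)) next
      mm5 <- mm_at(s, off, a5v)
      mm3 <- mm_at(s, off + pam_off + plen, chkv)
      ok <- fits & mm5 <= max_anchor_mm & mm3 <= max_anchor_mm
      if (!any(ok)) next
      tot <- mm5 + mm3
      better <- ok & tot < best_mm
      tie <- ok & tot == best_mm
      best_cnt[tie] <- best_cnt[tie] + 1L
      best_cnt[better] <- 1L
      best_mm[better] <- tot[better]
      if (any(better)) {
        idx <- which(better)
        best_pam[idx] <- substr(s[idx], off + pam_off,
                                off + pam_off + plen - 1L)
        best_codon[idx] <- substr(s[idx], off + codon_off,
                                  off + codon_off + 2L)
        best_strand[idx] <- strand
      }
    }
  }
  accepted <- is.finite(best_mm) & best_cnt == 1L &
    !grepl("N", best_pam, fixed = TRUE)
  pam <- best_pam
  if (template$pam_report_strand == "reverse_complement")
    pam[accepted] <- oracle_revcomp(pam[accepted])
  data.frame(
    accepted = accepted,
    pam = ifelse(accepted, pam, NA_character_),
    state = ifelse(accepted, classify_codon(ifelse(is.na(best_codon), "NNN",
                                                   best_codon)),
                   NA_character_),
    strand = ifelse(accepted, best_strand, NA_character_),
    stringsAsFactors = FALSE
  )
}

# Closed-form odds update for a deterministic two-strain round: lineages
# starting fully unedited with editing probabilities pi_f / pi_i and
# unedited relative fitness s multiply their odds by
# (pi + (1 - pi) s) per round (the edited part keeps fitness 1).
oracle_two_strain_odds <- function(odds0, pi_f, pi_i, s, rounds = 1L) {
  f <- c(un = odds0 / (odds0 + 1), ed = 0)
  i <- c(un = 1 / (odds0 + 1), ed = 0)
  step <- function(x, pi) {
    conv <- x["un"] * pi
    c(un = unname((x["un"] - conv) * s), ed = unname(x["ed"] + conv))
  }
  for (r in seq_len(rounds)) {
    f <- step(f, pi_f)
    i <- step(i, pi_i)
  }
  sum(f) / sum(i)
}

# sort a tally into canonical (pam) order and drop attributes, for
# count-for-count comparison
tally_counts <- function(tally) {
  df <- as.data.frame(tally)[, c("pam", "n_total", "n_TGG", "n_TGA",
                                 "n_TAG", "n_TAA", "n_other")]
  df <- df[df$n_total > 0, ]
  df <- df[order(df$pam), ]
  rownames(df) <- NULL
  df
}

# truth table -> per-PAM realized edited fraction
truth_edited_fraction <- function(truth) {
  tot <- tapply(truth$count, truth$pam, sum)
  ed <- tapply(truth$count * grepl("^EDITED", truth$state), truth$pam, sum)
  ef <- ed / tot
  ef[order(names(ef))]
}

uniform_256 <- function() {
  stats::setNames(rep(1, 256), enumerate_pams(4))
}

quiet_fastq <- function(read_set, path) {
  write_read_set(read_set, path)
  path
}
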