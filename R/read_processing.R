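# Read cleaning, anchor-based PAM/codon extraction, and per-PAM tallying.
#
# The locator scans each cleaned read and its reverse complement for the
# template's two constant segments (the 5' anchor and the constant part of
# anchor3 flanking the codon), allowing a bounded number of substitutions and
# no indels. A read contributes one observation only when a unique best
# placement exists; ties are rejected as ambiguous rather than guessed.

#' Cleaning parameters for raw amplicon reads
#'
#' @param max_n_frac Maximum tolerated fraction of `N` bases (default 0.1).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @param adapter_seq 3' adapter to trim; the read is cut where a prefix of
#'   the adapter of at least `adapter_seed` bases matches with at most
#'   `adapter_mm` mismatches. Empty string disables trimming.
#' @param adapter_seed Minimum adapter prefix length for a trim (default 10).
#' @param adapter_mm Mismatches tolerated in the adapter seed (default 1).
#' @param min_length Minimum post-trim read length; defaults (when `NA`) to
#'   the template span needed for extraction and is resolved inside
#'   [process_fastq()].
#' @return A list of class `cleaning_params`.
#' @export
cleaning_params <- function(max_n_frac = 0.1, min_mean_q = 20,
                            adapter_seq = "ACGACTTAGCAACAAGTCGCCTAGAAAGGT",
                            adapter_seed = 10L, adapter_mm = 1L,
                            min_length = NA_integer_) {
  if (max_n_frac < 0 || max_n_frac > 1)
    stop("max_n_frac must be in [0, 1]", call. = FALSE)
  if (nzchar(adapter_seq)) .check_dna(adapter_seq, "adapter_seq")
  structure(list(max_n_frac = max_n_frac, min_mean_q = min_mean_q,
                 adapter_seq = toupper(adapter_seq),
                 adapter_seed = as.integer(adapter_seed),
                 adapter_mm = as.integer(adapter_mm),
                 min_length = as.integer(min_length)),
            class = "cleaning_params")
}

CLEAN_REASONS <- c("adapter_only", "too_many_N", "low_quality", "too_short")
EXTRACT_REASONS <- c("no_anchor", "ambiguous", "ambiguous_pam")

#' Clean a set of raw reads
#'
#' Applies, in order: 3' adapter trimming, a poly-/many-N filter, a mean
#' quality filter, and a minimum-length filter.
#'
#' @param reads A `Biostrings::QualityScaledDNAStringSet`.
#' @param params A [cleaning_params()] with `min_length` resolved.
#' @return List with `reads` (kept, trimmed `QualityScaledDNAStringSet`),
#'   `keep` (logical over the input), and `reason` (character, `NA` for kept
#'   reads, otherwise one of `adapter_only`, `too_many_N`, `low_quality`,
#'   `too_short`).
#' @export
clean_reads <- function(reads, params) {
  stopifnot(inherits(params, "cleaning_params"))
  if (is.na(params$min_length))
    stop("params$min_length must be resolved before cleaning", call. = FALSE)
  n <- length(reads)
  reason <- rep(NA_character_, n)
  if (!n) return(list(reads = reads, keep = logical(0), reason = reason))

  seqs <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::quality(reads)

  # adapter trim: first occurrence of the adapter seed (<= adapter_mm
  # substitutions) cuts the read there
  if (nzchar(params$adapter_seq)) {
    seed <- substr(params$adapter_seq, 1L, params$adapter_seed)
    hits <- Biostrings::vmatchPattern(seed, seqs,
                                      max.mismatch = params$adapter_mm)
    first <- vapply(Biostrings::startIndex(hits), function(s)
      if (length(s)) min(s) else NA_integer_, integer(1))
    cut <- !is.na(first)
    if (any(cut)) {
      end <- ifelse(cut, first - 1L, Biostrings::width(seqs))
      seqs <- Biostrings::subseq(seqs, 1L, end)
      quals <- Biostrings::subseq(quals, 1L, end)
      reason[cut & end == 0L] <- "adapter_only"
    }
  }

  w <- Biostrings::width(seqs)
  nfrac <- ifelse(w > 0L,
                  Biostrings::letterFrequency(seqs, "N")[, 1] / pmax(w, 1L),
                  1)
  flag <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  flag(nfrac > params$max_n_frac, "too_many_N")

  qint <- methods::as(quals, "IntegerList")
  meanq <- ifelse(w > 0L, sum(qint) / pmax(w, 1L), 0)
  flag(meanq < params$min_mean_q, "low_quality")
  flag(w < params$min_length, "too_short")

  keep <- is.na(reason)
  kept <- Biostrings::QualityScaledDNAStringSet(seqs[keep], quals[keep])
  names(kept) <- names(reads)[keep]
  list(reads = kept, keep = keep, reason = reason)
}

# template-derived matching constants: the 5' anchor and the constant check
# segment of anchor3 immediately after the PAM slot, stopping before the
# codon slot (the codon itself varies with editing state).
.anchor_layout <- function(template) {
  check_len <- template$codon_slot[1] - template$pam_slot[2]
  list(
    anchor5 = template$anchor5,
    a5_len = nchar(template$anchor5),
    check_seq = substr(template$anchor3, 1L, check_len),
    check_len = check_len,
    # span from anchor5 start through codon end, all that extraction needs
    span = template$codon_slot[2]
  )
}

#' Extract per-read PAM observations by anchor matching
#'
#' For each read, both orientations are scanned for the template's 5' anchor
#' (at most `max_anchor_mm` substitutions, no indels). Each anchor hit
#' implies a template placement; the placement is accepted when the constant
#' segment between PAM slot and codon also matches with at most
#' `max_anchor_mm` substitutions and the full span through the codon lies
#' inside the read. Among accepted placements the unique one with fewest
#' total mismatches wins; ties or no hit reject the read (`ambiguous` /
#' `no_anchor`), and a PAM containing `N` rejects it as `ambiguous_pam`.
#'
#' @param reads Cleaned `QualityScaledDNAStringSet` (or `DNAStringSet`).
#' @param template An [amplicon_template()].
#' @param max_anchor_mm Substitutions tolerated in each anchor (default 2).
#' @return List with `obs` — data.frame `(read_id, pam, state, strand,
#'   anchor_mismatches)` for accepted reads — and `reason` (character per
#'   input read, `NA` when accepted).
#' @export
extract_observations <- function(reads, template, max_anchor_mm = 2L) {
  stopifnot(inherits(template, "amplicon_template"))
  lay <- .anchor_layout(template)
  seqs <- Biostrings::DNAStringSet(reads)
  n <- length(seqs)
  empty_obs <- data.frame(read_id = character(0), pam = character(0),
                          state = character(0), strand = character(0),
                          anchor_mismatches = integer(0),
                          stringsAsFactors = FALSE)
  if (!n) return(list(obs = empty_obs, reason = character(0)))

  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # candidate placements on both strands; offset = 1-based read position of
  # the anchor5 start
  cand <- list(
    fwd = .anchor_hits(seqs, lay, max_anchor_mm),
    rev = .anchor_hits(Biostrings::reverseComplement(seqs), lay,
                       max_anchor_mm)
  )
  chars <- list(fwd = as.character(seqs),
                rev = as.character(Biostrings::reverseComplement(seqs)))

  reason <- rep(NA_character_, n)
  out_pam <- out_state <- out_strand <- rep(NA_character_, n)
  out_mm <- rep(NA_integer_, n)

  pam_off <- template$pam_slot[1]      # offsets from anchor5 start (0-based)
  codon_off <- template$codon_slot[1]
  plen <- template$pam_length

  # fast vectorized path for the common case of exactly one anchor hit
  # across both orientations; everything else goes through the per-read scan
  nf <- lengths(cand$fwd)
  nr <- lengths(cand$rev)
  single <- which(nf + nr == 1L)
  if (length(single)) {
    strand1 <- ifelse(nf[single] == 1L, "fwd", "rev")
    take1 <- function(x) vapply(x, function(s)
      if (length(s)) s[1] else NA_integer_, integer(1))
    st1 <- ifelse(nf[single] == 1L, take1(cand$fwd[single]),
                  take1(cand$rev[single]))
    s1 <- ifelse(strand1 == "fwd", chars$fwd[single], chars$rev[single])
    fits <- st1 + lay$span - 1L <= nchar(s1)
    mm5 <- .hamming_at(s1, st1, lay$anchor5)
    mm3 <- .hamming_at(s1, st1 + pam_off + plen, lay$check_seq)
    ok <- fits & mm5 <= max_anchor_mm & mm3 <= max_anchor_mm
    reason[single[!ok]] <- "no_anchor"
    idx <- single[ok]
    if (length(idx)) {
      pam1 <- substr(s1[ok], st1[ok] + pam_off,
                     st1[ok] + pam_off + plen - 1L)
      has_n <- grepl("N", pam1, fixed = TRUE)
      reason[idx[has_n]] <- "ambiguous_pam"
      good <- !has_n
      if (template$pam_report_strand == "reverse_complement")
        pam1[good] <- revcomp(pam1[good])
      codon1 <- substr(s1[ok], st1[ok] + codon_off, st1[ok] + codon_off + 2L)
      out_pam[idx[good]] <- pam1[good]
      out_state[idx[good]] <- classify_codon(codon1[good])
      out_strand[idx[good]] <- strand1[ok][good]
      out_mm[idx[good]] <- (mm5 + mm3)[ok][good]
    }
  }

  for (i in which(nf + nr != 1L)) {
    placements <- NULL
    for (strand in c("fwd", "rev")) {
      starts <- cand[[strand]][[i]]
      if (!length(starts)) next
      s <- chars[[strand]][i]
      L <- nchar(s)
      for (st in starts) {
        if (st + lay$span - 1L > L) next
        mm5 <- .hamming(substr(s, st, st + lay$a5_len - 1L), lay$anchor5)
        chk_start <- st + pam_off + plen
        mm3 <- .hamming(substr(s, chk_start, chk_start + lay$check_len - 1L),
                        lay$check_seq)
        if (mm5 <= max_anchor_mm && mm3 <= max_anchor_mm)
          placements <- rbind(placements,
                              c(strand = strand, start = st,
                                mm = mm5 + mm3))
      }
    }
    if (is.null(placements)) { reason[i] <- "no_anchor"; next }
    mm <- as.integer(placements[, "mm"])
    best <- which(mm == min(mm))
    if (length(best) > 1L) { reason[i] <- "ambiguous"; next }
    strand <- placements[best, "strand"]
    st <- as.integer(placements[best, "start"])
    s <- chars[[strand]][i]
    pam <- substr(s, st + pam_off, st + pam_off + plen - 1L)
    if (grepl("N", pam, fixed = TRUE)) { reason[i] <- "ambiguous_pam"; next }
    if (template$pam_report_strand == "reverse_complement")
      pam <- revcomp(pam)
    codon <- substr(s, st + codon_off, st + codon_off + 2L)
    out_pam[i] <- pam
    out_state[i] <- classify_codon(codon)
    out_strand[i] <- strand
    out_mm[i] <- mm[best]
  }

  keep <- is.na(reason)
  obs <- data.frame(read_id = ids[keep], pam = out_pam[keep],
                    state = out_state[keep], strand = out_strand[keep],
                    anchor_mismatches = out_mm[keep],
                    stringsAsFactors = FALSE)
  list(obs = obs, reason = reason)
}

# Hamming anchor5 hits per read; returns an integer list of 1-based starts.
# N in the read never counts as a match (fixed = "subject" keeps the pattern
# literal while letting read Ns mismatch).
.anchor_hits <- function(seqs, lay, max_mm) {
  hits <- Biostrings::vmatchPattern(lay$anchor5, seqs, max.mismatch = max_mm,
                                    with.indels = FALSE)
  # plain-list accessor (NULL for no hit) avoids per-read S4 dispatch
  Biostrings::startIndex(hits)
}

# vectorized mismatch count of `pattern` placed at 1-based positions `at`
# of strings `s`; out-of-range positions count as mismatches
.hamming_at <- function(s, at, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  mm <- integer(length(s))
  for (j in seq_along(pat)) {
    mm <- mm + (substr(s, at + j - 1L, at + j - 1L) != pat[j])
  }
  mm
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(b) + 1L)  # out of bounds
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

#' Process FASTQ files into a per-PAM tally
#'
#' Streams every read of `files` through [clean_reads()] and
#' [extract_observations()], and accumulates per-PAM codon-state counts plus
#' full QC accounting. Deterministic for fixed inputs.
#'
#' @param files FASTQ path(s), optionally gzipped (Phred+33).
#' @param template An [amplicon_template()].
#' @param params A [cleaning_params()]; an unresolved `min_length` defaults
#'   to the template span needed for extraction.
#' @param max_anchor_mm Substitutions tolerated per anchor segment.
#' @return A `pam_tally`: data.frame with one row per observed PAM and
#'   columns `pam, n_total, n_TGG, n_TGA, n_TAG, n_TAA, n_other`, plus a
#'   `qc` attribute (`reads_in`, `reads_cleaned_out`, `reads_classified`,
#'   `rejected` counts by reason).
#' @export
process_fastq <- function(files, template, params = cleaning_params(),
                          max_anchor_mm = 2L) {
  stopifnot(inherits(template, "amplicon_template"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("cannot read FASTQ file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.na(params$min_length))
    params$min_length <- .anchor_layout(template)$span

  obs_list <- list()
  qc <- list(reads_in = 0L, reads_cleaned_out = 0L, reads_classified = 0L,
             rejected = stats::setNames(
               integer(length(CLEAN_REASONS) + length(EXTRACT_REASONS)),
               c(CLEAN_REASONS, EXTRACT_REASONS)))
  for (f in files) {
    reads <- .read_fastq(f)
    qc$reads_in <- qc$reads_in + length(reads)
    cl <- clean_reads(reads, params)
    tab <- table(cl$reason)
    qc$rejected[names(tab)] <- qc$rejected[names(tab)] + as.integer(tab)
    qc$reads_cleaned_out <- qc$reads_cleaned_out + length(cl$reads)
    ex <- extract_observations(cl$reads, template, max_anchor_mm)
    tab <- table(ex$reason)
    qc$rejected[names(tab)] <- qc$rejected[names(tab)] + as.integer(tab)
    qc$reads_classified <- qc$reads_classified + nrow(ex$obs)
    obs_list[[f]] <- ex$obs
  }
  obs <- do.call(rbind, obs_list)
  tally_from_observations(obs, qc = qc)
}

.read_fastq <- function(path) {
  # the reader stores FASTQ qualities via a metadata column and warns when
  # dropping it again; that warning carries no information here
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns on input", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Build a `pam_tally` from per-read observations
#'
#' @param obs data.frame with columns `pam` and `state` (as produced by
#'   [extract_observations()]); `NULL`/empty gives an all-zero tally.
#' @param qc Optional QC list stored as the `qc` attribute.
#' @return A `pam_tally` data.frame.
#' @export
tally_from_observations <- function(obs, qc = NULL) {
  cols <- c(UNEDITED_TGG = "n_TGG", EDITED_TGA = "n_TGA",
            EDITED_TAG = "n_TAG", EDITED_TAA = "n_TAA", OTHER = "n_other")
  if (is.null(obs) || !nrow(obs)) {
    tally <- data.frame(pam = character(0), n_total = integer(0),
                        n_TGG = integer(0), n_TGA = integer(0),
                        n_TAG = integer(0), n_TAA = integer(0),
                        n_other = integer(0), stringsAsFactors = FALSE)
  } else {
    pams <- sort(unique(obs$pam))
    counts <- table(factor(obs$pam, levels = pams),
                    factor(obs$state, levels = names(cols)))
    tally <- data.frame(pam = pams,
                        n_total = as.integer(rowSums(counts)),
                        stringsAsFactors = FALSE)
    for (s in names(cols)) tally[[cols[[s]]]] <- as.integer(counts[, s])
  }
  structure(tally, class = c("pam_tally", "data.frame"), qc = qc)
}

#' Tally accessors and I/O
#'
#' `tally_qc()` returns the QC accounting attached by [process_fastq()];
#' `write_tally()` / `read_tally()` round-trip the tally as TSV (the QC block
#' travels in a `.json` sidecar).
#'
#' @param tally A `pam_tally`.
#' @return `tally_qc`: the QC list (or `NULL`).
#' @export
tally_qc <- function(tally) attr(tally, "qc")

#' @rdname tally_qc
#' @param path TSV path.
#' @export
write_tally <- function(tally, path) {
  utils::write.table(as.data.frame(tally), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  qc <- tally_qc(tally)
  if (!is.null(qc)) {
    qc$rejected <- as.list(qc$rejected)
    jsonlite::write_json(qc, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname tally_qc
#' @export
read_tally <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$pam <- as.character(tab$pam)
  qc <- NULL
  if (file.exists(paste0(path, ".json"))) {
    qc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    qc$rejected <- unlist(qc$rejected)
  }
  structure(tab, class = c("pam_tally", "data.frame"), qc = qc)
}
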