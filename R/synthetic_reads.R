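# Synthetic amplicon FASTQ generation with paired ground truth.
#
# The generator emulates exactly the artifacts the cleaning stage removes:
# per-base substitution errors, N calls, 3' adapter tails, and reads emitted
# on either strand. Everything is driven by one integer seed and is
# reproducible byte for byte.

#' Per-base sequencing error model
#'
#' @param substitution_rate Probability a base is replaced by a different
#'   base (uniform over the three alternatives).
#' @param n_rate Probability a base is replaced by `N`.
#' @param adapter_seq 3' adapter sequence appended to a fraction of reads
#'   (empty string disables adapters).
#' @param adapter_rate Probability a read carries the adapter tail.
#' @param quality_high Phred score written for unperturbed bases.
#' @param quality_low Phred score written for substituted/N bases.
#' @return An object of class `read_error_model`.
#' @examples
#' error_model()                      # defaults
#' error_model(substitution_rate = 0)  # error-free reads
#' @export
error_model <- function(substitution_rate = 0.001, n_rate = 0.0005,
                        adapter_seq = "ACGACTTAGCAACAAGTCGCCTAGAAAGGT",
                        adapter_rate = 0, quality_high = 37L,
                        quality_low = 11L) {
  probs <- c(substitution_rate, n_rate, adapter_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (nzchar(adapter_seq)) .check_dna(adapter_seq, "adapter_seq")
  q <- c(quality_high, quality_low)
  if (any(q < 2L) || any(q > 41L))
    stop("Phred scores must lie in [2, 41]", call. = FALSE)
  structure(list(substitution_rate = substitution_rate, n_rate = n_rate,
                 adapter_seq = toupper(adapter_seq),
                 adapter_rate = adapter_rate,
                 quality_high = as.integer(quality_high),
                 quality_low = as.integer(quality_low)),
            class = "read_error_model")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Two-strain mixture weights
#'
#' Builds the weight map for a spiked mixing experiment in which a strain
#' carrying a functional PAM is deliberately mixed into a majority of
#' invalid-PAM cells (e.g. 1:15 when the functional class is 1/16 of a
#' library, or 1:99 for a sensitivity test).
#'
#' @param ratio Length-2 positive numeric `c(functional, invalid)` parts.
#' @param functional_pam,invalid_pam Distinct PAM sequences.
#' @return Named numeric weight vector.
#' @examples
#' make_mixture_weights(c(1, 15), "GGGG", "TTTT")
#' @export
make_mixture_weights <- function(ratio, functional_pam, invalid_pam) {
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be two positive numbers", call. = FALSE)
  functional_pam <- toupper(functional_pam)
  invalid_pam <- toupper(invalid_pam)
  if (identical(functional_pam, invalid_pam))
    stop("functional and invalid PAMs must be distinct", call. = FALSE)
  stats::setNames(as.numeric(ratio), c(functional_pam, invalid_pam))
}

#' Generate a synthetic amplicon read set with ground truth
#'
#' Draws each read's PAM from the normalized `weights`, sets its codon state
#' to edited with probability `edited_fraction[pam]` (splitting edits across
#' TGA/TAA/TAG by `edit_split`), builds the exact amplicon with
#' [synthesize_amplicon()], then corrupts it through the error model:
#' per-base substitutions, N calls, an optional 3' adapter tail, and
#' reverse-complement emission with probability `revcomp_prob`.
#'
#' The default `edit_split` of 0.5/0.3/0.2 (TGA/TAA/TAG) reproduces the
#' outcome ordering typical of cytosine editors at this codon — TGA most
#' frequent, TAG least — the magnitudes being a configuration choice.
#'
#' @param weights Named non-negative numeric vector, PAM -> sampling weight.
#' @param edited_fraction Either a single probability applied to every PAM or
#'   a named vector parallel to `weights`.
#' @param template An [amplicon_template()].
#' @param n_reads Number of reads to generate.
#' @param error_model An [error_model()].
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param edit_split Probabilities of the `EDITED_TGA`, `EDITED_TAA`,
#'   `EDITED_TAG` outcomes given that a read is edited (normalized
#'   internally).
#' @param revcomp_prob Probability a read is emitted reverse complemented.
#'
#' @return A list of class `read_set`:
#'   * `reads` — `Biostrings::QualityScaledDNAStringSet` (Phred+33);
#'   * `truth` — data.frame `(pam, state, count)` of realized ground-truth
#'     counts (class `truth_table`, with `seed`, `n_reads` attributes);
#'   * `truth_reads` — per-read data.frame `(pam, state, strand)`.
#' @export
generate_library_reads <- function(weights, edited_fraction, template,
                                   n_reads,
                                   error_model = pamscreen::error_model(),
                                   seed = 1L,
                                   edit_split = c(TGA = 0.5, TAA = 0.3,
                                                  TAG = 0.2),
                                   revcomp_prob = 0.5) {
  stopifnot(inherits(template, "amplicon_template"),
            inherits(error_model, "read_error_model"))
  if (!length(weights) || is.null(names(weights)))
    stop("weights must be a named PAM -> weight vector", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  if (length(n_reads) != 1L || is.na(n_reads) || n_reads < 1)
    stop("n_reads must be a positive integer", call. = FALSE)
  n_reads <- as.integer(n_reads)
  pams <- toupper(names(weights))
  if (any(nchar(pams) != template$pam_length))
    stop("all PAMs must have template$pam_length bases", call. = FALSE)
  if (length(edited_fraction) == 1L && is.null(names(edited_fraction)))
    edited_fraction <- stats::setNames(rep(edited_fraction, length(pams)),
                                       pams)
  ef <- edited_fraction[pams]
  if (any(is.na(ef)) || any(ef < 0) || any(ef > 1))
    stop("edited_fraction must give a probability for every PAM",
         call. = FALSE)
  if (length(edit_split) != 3L || any(edit_split < 0) || sum(edit_split) <= 0)
    stop("edit_split must be three non-negative weights", call. = FALSE)
  split_states <- c("EDITED_TGA", "EDITED_TAA", "EDITED_TAG")
  edit_split <- edit_split / sum(edit_split)

  with_seed(seed, {
    pam_idx <- sample.int(length(pams), n_reads, replace = TRUE,
                          prob = weights / sum(weights))
    edited <- stats::runif(n_reads) < ef[pam_idx]
    state <- rep("UNEDITED_TGG", n_reads)
    state[edited] <- sample(split_states, sum(edited), replace = TRUE,
                            prob = edit_split)

    # one exact sequence per realized (pam, state) genotype
    combo <- paste(pam_idx, state)
    ucombo <- unique(combo)
    base_seq <- vapply(strsplit(ucombo, " ", fixed = TRUE), function(z) {
      synthesize_amplicon(template, pams[as.integer(z[1])], z[2])
    }, character(1))
    seqs <- base_seq[match(combo, ucombo)]

    len <- template$total_length
    qual <- rep(strrep(.phred_char(error_model$quality_high), len), n_reads)
    low_q <- .phred_char(error_model$quality_low)

    # per-base substitutions, then N calls, on the template-strand sequence
    seqs_qual <- .corrupt_bases(seqs, qual, error_model, low_q)
    seqs <- seqs_qual$seqs
    qual <- seqs_qual$qual

    is_rev <- stats::runif(n_reads) < revcomp_prob
    if (any(is_rev)) {
      seqs[is_rev] <- revcomp(seqs[is_rev])
      # quality strings are uniform except at corrupted bases, so only those
      # actually need reversing
      flip <- is_rev & (qual != strrep(.phred_char(error_model$quality_high),
                                       len))
      qual[flip] <- vapply(strsplit(qual[flip], ""), function(q)
        paste(rev(q), collapse = ""), character(1))
    }

    if (nzchar(error_model$adapter_seq) && error_model$adapter_rate > 0) {
      with_ad <- stats::runif(n_reads) < error_model$adapter_rate
      ad_q <- strrep(.phred_char(error_model$quality_high),
                     nchar(error_model$adapter_seq))
      seqs[with_ad] <- paste0(seqs[with_ad], error_model$adapter_seq)
      qual[with_ad] <- paste0(qual[with_ad], ad_q)
    }

    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(qual))
    names(reads) <- sprintf("read_%07d", seq_len(n_reads))

    truth_reads <- data.frame(pam = pams[pam_idx], state = state,
                              strand = ifelse(is_rev, "rev", "fwd"),
                              stringsAsFactors = FALSE)
    truth <- .truth_from_reads(truth_reads, seed, n_reads)
    structure(list(reads = reads, truth = truth, truth_reads = truth_reads),
              class = "read_set")
  })
}

.phred_char <- function(q) rawToChar(as.raw(q + 33L))

.corrupt_bases <- function(seqs, qual, em, low_q) {
  p_any <- em$substitution_rate + em$n_rate
  if (p_any <= 0) return(list(seqs = seqs, qual = qual))
  n_err <- stats::rbinom(length(seqs), nchar(seqs), p_any)
  p_n <- em$n_rate / p_any
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      if (stats::runif(1) < p_n) {
        substr(seqs[i], p, p) <- "N"
      } else {
        cur <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
      substr(qual[i], p, p) <- low_q
    }
  }
  list(seqs = seqs, qual = qual)
}

.truth_from_reads <- function(truth_reads, seed, n_reads) {
  tab <- stats::aggregate(count ~ pam + state,
                          data = cbind(truth_reads[c("pam", "state")],
                                       count = 1L),
                          FUN = sum)
  tab <- tab[order(tab$pam, match(tab$state, CODON_STATES)), ]
  rownames(tab) <- NULL
  structure(tab, class = c("truth_table", "data.frame"),
            seed = seed, n_reads = n_reads)
}

#' Write a generated read set to FASTQ (+ truth sidecars)
#'
#' Writes Phred+33 FASTQ (gzip when the path ends in `.gz`), the truth table
#' as TSV (`pam`, `state`, `count`) and a JSON sidecar recording seed and
#' read count.
#'
#' @param read_set A `read_set` from [generate_library_reads()].
#' @param fastq_path Output FASTQ path (`.gz` accepted).
#' @param truth_path Optional truth-table TSV path; default alongside FASTQ.
#' @return `fastq_path`, invisibly.
#' @export
write_read_set <- function(read_set, fastq_path, truth_path = NULL) {
  stopifnot(inherits(read_set, "read_set"))
  compress <- grepl("\\.gz$", fastq_path)
  Biostrings::writeQualityScaledXStringSet(read_set$reads, fastq_path,
                                           compress = compress)
  if (is.null(truth_path))
    truth_path <- paste0(sub("\\.gz$", "", fastq_path), ".truth.tsv")
  write_truth_table(read_set$truth, truth_path)
  invisible(fastq_path)
}

#' @rdname write_read_set
#' @param truth A `truth_table` data.frame.
#' @param path TSV output path (a `.json` sidecar with seed/read count is
#'   written next to it).
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(seed = attr(truth, "seed"), n_reads = attr(truth, "n_reads"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path TSV path.
#' @return A `truth_table` data.frame.
#' @export
read_truth_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer"))
  meta_path <- paste0(path, ".json")
  seed <- n_reads <- NA
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    seed <- meta$seed
    n_reads <- meta$n_reads
  }
  structure(tab, class = c("truth_table", "data.frame"),
            seed = seed, n_reads = n_reads)
}
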