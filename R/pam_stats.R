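# Per-PAM statistics: base-editing efficiency, mutation-pattern
# distribution, library frequencies and uniformity, enrichment factors, and
# functional/enriched calls.

#' Per-PAM base-editing efficiency
#'
#' Fraction of classified reads for a PAM that carry a stop-codon conversion
#' at the target codon: `(n_TGA + n_TAG + n_TAA) / n_total`. `OTHER` codons
#' (unexplained 3-mers, typically sequencing errors) stay in the denominator
#' but never count as edits.
#'
#' @param tally A `pam_tally` (or any data.frame with the count columns).
#' @return Numeric vector parallel to the tally rows; `NA` where
#'   `n_total == 0` (undefined, not zero).
#' @examples
#' be_efficiency(data.frame(n_total = 100, n_TGG = 20, n_TGA = 50,
#'                          n_TAG = 10, n_TAA = 20, n_other = 0))  # 0.8
#' @export
be_efficiency <- function(tally) {
  edited <- tally$n_TGA + tally$n_TAG + tally$n_TAA
  ifelse(tally$n_total > 0, edited / tally$n_total, NA_real_)
}

#' Distribution of editing outcomes at the target codon
#'
#' Normalized proportions of the three stop-codon outcomes (TGA, TAA, TAG),
#' pooled across PAMs or per PAM.
#'
#' @param tally A `pam_tally`.
#' @param per_pam If `TRUE`, return one row per PAM instead of the pooled
#'   distribution.
#' @return Named numeric vector `c(TGA, TAA, TAG)` (pooled), or a data.frame
#'   with those columns per PAM. Pooled result is `NA` when no edited reads
#'   exist.
#' @export
mutation_pattern <- function(tally, per_pam = FALSE) {
  if (per_pam) {
    tot <- tally$n_TGA + tally$n_TAA + tally$n_TAG
    return(data.frame(pam = tally$pam,
                      TGA = ifelse(tot > 0, tally$n_TGA / tot, NA_real_),
                      TAA = ifelse(tot > 0, tally$n_TAA / tot, NA_real_),
                      TAG = ifelse(tot > 0, tally$n_TAG / tot, NA_real_),
                      stringsAsFactors = FALSE))
  }
  counts <- c(TGA = sum(tally$n_TGA), TAA = sum(tally$n_TAA),
              TAG = sum(tally$n_TAG))
  if (sum(counts) == 0) {
    warning("no edited reads; mutation pattern undefined")
    return(counts * NA_real_)
  }
  counts / sum(counts)
}

#' Enrichment factor of a PAM between the initial and enriched libraries
#'
#' The enrichment factor of PAM p is the proportion of reads with PAM p that
#' underwent base editing in the enriched library, divided by the proportion
#' of all reads with PAM p in the initial library. It is undefined (`NA`)
#' for PAMs absent from the initial library. Setting
#' `numerator = "all"` replaces the edited-read numerator by all reads of p
#' in the enriched library, for sensitivity analysis.
#'
#' @param initial,enriched `pam_tally` objects for the two libraries.
#' @param pam Optional PAM(s) to report; default is the union of both
#'   libraries.
#' @param numerator `"edited"` (default) or `"all"`.
#' @return Named numeric vector of enrichment factors (`NA` = undefined).
#' @export
enrichment_factor <- function(initial, enriched, pam = NULL,
                              numerator = c("edited", "all")) {
  numerator <- match.arg(numerator)
  if (!nrow(initial) || !nrow(enriched))
    stop("both tallies must be non-empty", call. = FALSE)
  if (is.null(pam)) pam <- sort(union(initial$pam, enriched$pam))
  tot_init <- sum(initial$n_total)
  tot_enr <- sum(enriched$n_total)
  i <- match(pam, initial$pam)
  e <- match(pam, enriched$pam)
  n_init <- ifelse(is.na(i), 0L, initial$n_total[i])
  num <- if (numerator == "edited") {
    ifelse(is.na(e), 0,
           enriched$n_TGA[e] + enriched$n_TAG[e] + enriched$n_TAA[e])
  } else {
    ifelse(is.na(e), 0, enriched$n_total[e])
  }
  p_init <- n_init / tot_init
  p_enr <- num / tot_enr
  stats::setNames(ifelse(p_init > 0, p_enr / p_init, NA_real_), pam)
}

#' Combined per-PAM statistics table
#'
#' Assembles the per-PAM summary used by the reporting stage: efficiency in
#' the enriched library, library frequencies, enrichment factor, and the
#' functional/enriched calls at their (strict) thresholds.
#'
#' @inheritParams enrichment_factor
#' @param functional_threshold Efficiency above which a PAM is called
#'   functional (strict `>`, default 0.01 — i.e. more than 1% of its reads
#'   edited).
#' @param enriched_threshold Enrichment factor above which a PAM is called
#'   enriched (strict `>`, default 1).
#' @return A `pam_stats` data.frame with columns `pam, n_initial,
#'   n_enriched, efficiency, freq_initial, freq_enriched_edited,
#'   enrichment_factor, functional, enriched`; thresholds and the numerator
#'   convention are stored as attributes.
#' @export
pam_stats <- function(initial, enriched, functional_threshold = 0.01,
                      enriched_threshold = 1,
                      numerator = c("edited", "all")) {
  numerator <- match.arg(numerator)
  pam <- sort(union(initial$pam, enriched$pam))
  i <- match(pam, initial$pam)
  e <- match(pam, enriched$pam)
  n_init <- ifelse(is.na(i), 0L, initial$n_total[i])
  n_enr <- ifelse(is.na(e), 0L, enriched$n_total[e])
  eff <- rep(NA_real_, length(pam))
  eff[!is.na(e)] <- be_efficiency(enriched[e[!is.na(e)], ])
  edited_enr <- ifelse(is.na(e), 0,
                       enriched$n_TGA[e] + enriched$n_TAG[e] +
                         enriched$n_TAA[e])
  ef <- enrichment_factor(initial, enriched, pam, numerator = numerator)
  out <- data.frame(
    pam = pam,
    n_initial = n_init,
    n_enriched = n_enr,
    efficiency = eff,
    freq_initial = n_init / sum(initial$n_total),
    freq_enriched_edited = edited_enr / sum(enriched$n_total),
    enrichment_factor = unname(ef),
    stringsAsFactors = FALSE
  )
  out$functional <- call_functional(out, functional_threshold)
  out$enriched <- call_enriched(out, enriched_threshold)
  structure(out, class = c("pam_stats", "data.frame"),
            functional_threshold = functional_threshold,
            enriched_threshold = enriched_threshold,
            ef_numerator = numerator)
}

#' Functional / enriched calls
#'
#' Both calls use strict inequalities: a PAM is functional when more than
#' `threshold` of its reads are edited, and enriched when its enrichment
#' factor exceeds `threshold`; boundary values and undefined statistics are
#' negative.
#'
#' @param stats A `pam_stats` data.frame (or any frame with `efficiency` /
#'   `enrichment_factor`).
#' @param threshold Strict cut-off (defaults 0.01 and 1).
#' @return Logical vector.
#' @export
call_functional <- function(stats, threshold = 0.01) {
  !is.na(stats$efficiency) & stats$efficiency > threshold
}

#' @rdname call_functional
#' @export
call_enriched <- function(stats, threshold = 1) {
  !is.na(stats$enrichment_factor) & stats$enrichment_factor > threshold
}

#' Fold enrichment of a strain proportion across screening
#'
#' Ratio of the final to the initial proportion of a (typically functional)
#' genotype, e.g. 7.3% rising to 67.6% is a 9.26-fold — reported as 9-fold —
#' enrichment. `round_fold()` applies the reporting convention
#' (round half away from zero to an integer).
#'
#' @param p_initial Initial proportion, in (0, 1].
#' @param p_final Final proportion, in [0, 1].
#' @return Numeric fold change.
#' @examples
#' fold_enrichment(0.073, 0.676)             # 9.26
#' round_fold(fold_enrichment(0.073, 0.676)) # 9
#' @export
fold_enrichment <- function(p_initial, p_final) {
  if (any(!is.finite(p_initial)) || any(p_initial <= 0) ||
      any(p_initial > 1))
    stop("p_initial must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(p_final)) || any(p_final < 0) || any(p_final > 1))
    stop("p_final must lie in [0, 1]", call. = FALSE)
  p_final / p_initial
}

#' @rdname fold_enrichment
#' @param x Numeric fold values.
#' @export
round_fold <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Library uniformity check
#'
#' A randomized PAM library is expected to be near-uniform after construction
#' and carrier-marker selection. With only `4^k` categories, uniformity is
#' assessed by a chi-square goodness-of-fit test against the flat `1/4^k`
#' expectation plus the coefficient of variation of per-PAM frequencies.
#'
#' @param tally A `pam_tally` of the initial library.
#' @param k PAM length (default inferred from the tally); absent PAMs enter
#'   as zero-count cells.
#' @return List `chi2`, `df`, `p_value`, `cv`, `min_freq`, `max_freq`.
#' @export
uniformity_check <- function(tally, k = NULL) {
  if (sum(tally$n_total > 0) < 2L) {
    warning("fewer than two PAMs with counts; uniformity undefined")
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                cv = NA_real_, min_freq = NA_real_, max_freq = NA_real_))
  }
  if (is.null(k)) k <- unique(nchar(tally$pam))
  stopifnot(length(k) == 1L)
  all_pams <- enumerate_pams(k)
  counts <- stats::setNames(rep(0L, length(all_pams)), all_pams)
  counts[tally$pam] <- tally$n_total
  n <- sum(counts)
  expected <- n / length(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  freq <- counts / n
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       cv = stats::sd(freq) / mean(freq),
       min_freq = min(freq), max_freq = max(freq))
}

#' Merge replicate per-PAM statistics tables
#'
#' Keeps each replicate's efficiency and enrichment factor as suffixed
#' columns, adds their arithmetic means, and calls a PAM functional/enriched
#' in consensus only when every replicate calls it so.
#'
#' @param tables List of `pam_stats` tables over the same PAM set.
#' @return A merged `pam_stats`-like data.frame with per-replicate columns
#'   (`efficiency_rep1`, ...), `efficiency` / `enrichment_factor` means, and
#'   consensus `functional` / `enriched` flags.
#' @export
merge_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  pam <- tables[[1]]$pam
  for (j in seq_along(tables)) {
    extra <- c(setdiff(tables[[j]]$pam, pam), setdiff(pam, tables[[j]]$pam))
    if (length(extra))
      stop("replicate ", j, " has a mismatched PAM set: ",
           paste(utils::head(extra, 10), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(pam = pam, stringsAsFactors = FALSE)
  effs <- efs <- matrix(NA_real_, nrow = length(pam), ncol = length(tables))
  fun <- enr <- matrix(NA, nrow = length(pam), ncol = length(tables))
  for (j in seq_along(tables)) {
    t_j <- tables[[j]][match(pam, tables[[j]]$pam), ]
    effs[, j] <- t_j$efficiency
    efs[, j] <- t_j$enrichment_factor
    fun[, j] <- t_j$functional
    enr[, j] <- t_j$enriched
    out[[paste0("efficiency_rep", j)]] <- t_j$efficiency
    out[[paste0("enrichment_factor_rep", j)]] <- t_j$enrichment_factor
  }
  out$efficiency <- rowMeans(effs)
  out$enrichment_factor <- rowMeans(efs)
  out$functional <- apply(fun, 1, all)
  out$enriched <- apply(enr, 1, all)
  structure(out, class = c("pam_stats", "data.frame"),
            n_replicates = length(tables))
}

#' Read / write a per-PAM statistics table as TSV
#'
#' Column order is fixed and documented: `pam, n_initial, n_enriched,
#' efficiency, freq_initial, freq_enriched_edited, enrichment_factor,
#' functional, enriched` (replicate columns, when present, follow).
#'
#' @param stats A `pam_stats` data.frame.
#' @param path TSV path.
#' @export
write_pam_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pam_stats
#' @export
read_pam_stats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$pam <- as.character(tab$pam)
  structure(tab, class = c("pam_stats", "data.frame"))
}
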