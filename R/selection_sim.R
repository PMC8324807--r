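# Population dynamics of the survival screen: editing induction,
# differential 5-fluorouracil survival of edited (counterselection-escaped)
# vs unedited genotypes, and colony-bottleneck sampling between rounds.

#' Screening-round parameters
#'
#' One screening round is modeled as (i) induction — unedited cells of PAM p
#' become edited with probability `edit_prob[p] + background_escape`;
#' (ii) selection/growth — edited lineages keep relative fitness 1 while
#' unedited (still counterselectable) lineages are scaled by
#' `unedited_survival`; (iii) renormalization, and in stochastic mode a
#' multinomial colony bottleneck of `bottleneck_size` cells.
#'
#' Defaults: the canonical-PAM induction probability is 0.1 (about one cell
#' in ten survives counterselection after a single induction with the
#' canonical PAM), the bottleneck is 1e5 harvested colonies, the unedited
#' relative fitness under 5-FU is 0.02, and a small background escape rate
#' (1e-6 per round) models spontaneous inactivation of the
#' counterselectable gene.
#'
#' @param edit_prob Named vector, PAM -> per-round editing probability; a
#'   single unnamed value applies to every PAM in the population.
#' @param background_escape Spontaneous escape probability per round.
#' @param unedited_survival Relative fitness `s` of unedited cells per round
#'   (`s < 1` is counterselection).
#' @param bottleneck_size Colonies harvested per round (stochastic mode).
#' @param rounds Number of screening rounds.
#' @param mode `"deterministic"` (expected dynamics) or `"stochastic"`
#'   (binomial induction + multinomial bottleneck).
#' @param seed Integer seed for stochastic mode.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(edit_prob = 0.1, background_escape = 1e-6,
                          unedited_survival = 0.02,
                          bottleneck_size = 1e5L, rounds = 2L,
                          mode = c("deterministic", "stochastic"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (any(edit_prob < 0) || any(edit_prob > 1))
    stop("edit_prob entries must be probabilities", call. = FALSE)
  if (background_escape < 0 || background_escape > 1)
    stop("background_escape must be a probability", call. = FALSE)
  if (unedited_survival < 0 || unedited_survival > 1)
    stop("unedited_survival must lie in [0, 1]", call. = FALSE)
  if (bottleneck_size < 1) stop("bottleneck_size must be >= 1",
                                call. = FALSE)
  structure(list(edit_prob = edit_prob,
                 background_escape = background_escape,
                 unedited_survival = unedited_survival,
                 bottleneck_size = as.integer(bottleneck_size),
                 rounds = as.integer(rounds), mode = mode,
                 seed = as.integer(seed)),
            class = "screen_params")
}

#' Initialize a screen population
#'
#' @param weights Named vector, PAM -> initial abundance weight.
#' @param edited_fraction Initially edited fraction per PAM (single value or
#'   named vector), usually 0 before the first induction.
#' @param total Total abundance (proportions scale to this).
#' @return A `screen_population`: data.frame `(pam, edited, abundance)` with
#'   a `round` attribute of 0.
#' @examples
#' init_population(make_mixture_weights(c(1, 15), "GGGG", "TTTT"))
#' @export
init_population <- function(weights, edited_fraction = 0, total = 1) {
  if (!length(weights) || is.null(names(weights)))
    stop("weights must be a named PAM -> weight vector", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  pams <- names(weights)
  if (length(edited_fraction) == 1L && is.null(names(edited_fraction)))
    edited_fraction <- stats::setNames(rep(edited_fraction, length(pams)),
                                       pams)
  ef <- edited_fraction[pams]
  if (any(is.na(ef)) || any(ef < 0) || any(ef > 1))
    stop("edited_fraction must give a probability for every PAM",
         call. = FALSE)
  w <- weights / sum(weights) * total
  pop <- data.frame(pam = rep(pams, each = 2L),
                    edited = rep(c(FALSE, TRUE), length(pams)),
                    abundance = as.vector(rbind(w * (1 - ef), w * ef)),
                    stringsAsFactors = FALSE)
  structure(pop, class = c("screen_population", "data.frame"), round = 0L)
}

.edit_prob_for <- function(params, pams) {
  ep <- params$edit_prob
  if (is.null(names(ep))) {
    if (length(ep) != 1L)
      stop("unnamed edit_prob must be a single value", call. = FALSE)
    return(stats::setNames(rep(ep, length(pams)), pams))
  }
  out <- ep[pams]
  if (any(is.na(out)))
    stop("edit_prob missing for PAM(s): ",
         paste(pams[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Advance the screen population by one round
#'
#' @param pop A `screen_population`.
#' @param params A [screen_params()]. In stochastic mode the RNG stream is
#'   used as-is — seed control belongs to [run_screen()].
#' @return The population after induction, selection and renormalization
#'   (plus a multinomial bottleneck in stochastic mode); `round` is
#'   incremented.
#' @export
simulate_round <- function(pop, params) {
  stopifnot(inherits(pop, "screen_population"),
            inherits(params, "screen_params"))
  pams <- unique(pop$pam)
  pi_p <- pmin(.edit_prob_for(params, pams) + params$background_escape, 1)
  un <- !pop$edited
  p_conv <- pi_p[pop$pam[un]]

  if (params$mode == "stochastic") {
    conv <- stats::rbinom(sum(un), round(pop$abundance[un]), p_conv)
  } else {
    conv <- pop$abundance[un] * p_conv
  }
  new_ab <- pop$abundance
  new_ab[un] <- new_ab[un] - conv
  key <- match(paste(pop$pam, TRUE), paste(pop$pam, pop$edited))
  new_ab[key[un]] <- new_ab[key[un]] + conv

  # counterselection: unedited lineages scaled by s
  new_ab[un] <- new_ab[un] * params$unedited_survival

  tot <- sum(new_ab)
  if (tot <= 0) stop("population went extinct", call. = FALSE)
  prop <- new_ab / tot

  if (params$mode == "stochastic") {
    new_ab <- as.numeric(stats::rmultinom(1, params$bottleneck_size, prop))
  } else {
    new_ab <- prop
  }
  out <- pop
  out$abundance <- new_ab
  attr(out, "round") <- attr(pop, "round") + 1L
  out
}

#' Proportions of a screen population
#'
#' @param pop A `screen_population`.
#' @return The population with `abundance` replaced by `proportion`
#'   (summing to 1).
#' @export
population_proportions <- function(pop) {
  out <- as.data.frame(pop)
  out$proportion <- out$abundance / sum(out$abundance)
  out$abundance <- NULL
  out
}

#' Run a multi-round screen
#'
#' Applies [simulate_round()] `params$rounds` times under `params$seed`
#' (stochastic mode) and records, per round, each PAM's total proportion and
#' edited fraction.
#'
#' @param init A `screen_population` from [init_population()].
#' @param params A [screen_params()].
#' @return A list of class `screen_trajectory`: `populations` (per-round
#'   `screen_population`s, element 1 = initial) and `summary` — data.frame
#'   `(round, pam, proportion, edited_fraction)`.
#' @export
run_screen <- function(init, params) {
  stopifnot(inherits(init, "screen_population"),
            inherits(params, "screen_params"))
  run <- function() {
    pops <- vector("list", params$rounds + 1L)
    pops[[1]] <- init
    for (r in seq_len(params$rounds))
      pops[[r + 1L]] <- simulate_round(pops[[r]], params)
    pops
  }
  pops <- if (params$mode == "stochastic") with_seed(params$seed, run())
          else run()
  summary <- do.call(rbind, lapply(seq_along(pops), function(j) {
    p <- population_proportions(pops[[j]])
    agg_tot <- tapply(p$proportion, p$pam, sum)
    agg_ed <- tapply(p$proportion * p$edited, p$pam, sum)
    data.frame(round = j - 1L, pam = names(agg_tot),
               proportion = as.numeric(agg_tot),
               edited_fraction = ifelse(agg_tot > 0,
                                        as.numeric(agg_ed) / agg_tot, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(populations = pops, summary = summary),
            class = "screen_trajectory")
}

#' Write a screen trajectory summary as TSV
#'
#' @param trajectory A `screen_trajectory`.
#' @param path TSV path (columns `round, pam, proportion, edited_fraction`).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sequence a screen population into synthetic reads
#'
#' Bridges the simulator to the sequencing pipeline: the population's
#' per-PAM proportions become library weights and its per-PAM edited
#' fractions become editing probabilities for
#' [generate_library_reads()].
#'
#' @param pop A `screen_population`.
#' @param template An [amplicon_template()].
#' @param n_reads Number of reads.
#' @param error_model An [error_model()].
#' @param seed Integer seed.
#' @param ... Passed to [generate_library_reads()].
#' @return A `read_set` (see [generate_library_reads()]).
#' @export
couple_to_reads <- function(pop, template, n_reads,
                            error_model = pamscreen::error_model(),
                            seed = 1L, ...) {
  stopifnot(inherits(pop, "screen_population"))
  p <- population_proportions(pop)
  tot <- tapply(p$proportion, p$pam, sum)
  ed <- tapply(p$proportion * p$edited, p$pam, sum)
  keep <- tot > 0
  weights <- tot[keep]
  ef <- ifelse(tot[keep] > 0, ed[keep] / tot[keep], 0)
  generate_library_reads(weights = weights,
                         edited_fraction = stats::setNames(ef,
                                                           names(weights)),
                         template = template, n_reads = n_reads,
                         error_model = error_model, seed = seed, ...)
}
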