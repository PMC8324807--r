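# End-to-end orchestration: a single YAML config drives
# simulate -> process -> stats -> report, with provenance (resolved config,
# seed, checksummed artifact manifest) written next to the outputs.

#' Build a validated run configuration
#'
#' A run configuration collects everything an end-to-end screen analysis
#' needs: the amplicon template, simulator parameters, read-generator
#' settings, cleaning parameters, statistic thresholds, the output
#' directory and the global seed. Unspecified fields fall back to package
#' defaults; the fully resolved configuration is written next to every
#' run's outputs.
#'
#' @param outdir Output directory.
#' @param seed Global integer seed (drives simulator and generator).
#' @param template An [amplicon_template()] (default [default_template()]).
#' @param n_pams Library PAM diversity: the first `n_pams` of
#'   `enumerate_pams(template$pam_length)` form the library (default all).
#' @param n_active Number of active PAMs (assigned `edit_prob`); the first
#'   `n_active` of the library in enumeration order.
#' @param edit_prob Induction probability of active PAMs (default 0.1) or a
#'   full named PAM vector.
#' @param rounds Screening rounds (default 2).
#' @param unedited_survival,background_escape,bottleneck_size,mode See
#'   [screen_params()].
#' @param n_reads Reads sequenced per library (default 2e5).
#' @param error_model An [error_model()].
#' @param cleaning A [cleaning_params()].
#' @param max_anchor_mm Anchor mismatch tolerance (default 2).
#' @param functional_threshold,enriched_threshold Call thresholds
#'   (defaults 0.01 and 1, strict).
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, template = default_template(),
                       n_pams = NULL, n_active = 40L, edit_prob = 0.1,
                       rounds = 2L, unedited_survival = 0.02,
                       background_escape = 1e-6, bottleneck_size = 1e5L,
                       mode = "stochastic", n_reads = 2e5,
                       error_model = pamscreen::error_model(),
                       cleaning = cleaning_params(), max_anchor_mm = 2L,
                       functional_threshold = 0.01,
                       enriched_threshold = 1) {
  stopifnot(inherits(template, "amplicon_template"),
            inherits(error_model, "read_error_model"),
            inherits(cleaning, "cleaning_params"))
  library_pams <- enumerate_pams(template$pam_length)
  if (!is.null(n_pams)) library_pams <- library_pams[seq_len(n_pams)]
  if (is.null(names(edit_prob))) {
    if (length(edit_prob) != 1L)
      stop("unnamed edit_prob must be a single probability", call. = FALSE)
    if (n_active < 0L || n_active > length(library_pams))
      stop("n_active must lie in [0, number of library PAMs]",
           call. = FALSE)
    ep <- stats::setNames(rep(0, length(library_pams)), library_pams)
    ep[seq_len(n_active)] <- edit_prob
    edit_prob <- ep
  } else if (!all(names(edit_prob) %in% library_pams)) {
    stop("edit_prob names must be library PAMs", call. = FALSE)
  }
  structure(list(
    outdir = outdir, seed = as.integer(seed), template = template,
    library_pams = library_pams, edit_prob = edit_prob, rounds = rounds,
    unedited_survival = unedited_survival,
    background_escape = background_escape,
    bottleneck_size = bottleneck_size, mode = mode,
    n_reads = as.integer(n_reads), error_model = error_model,
    cleaning = cleaning, max_anchor_mm = as.integer(max_anchor_mm),
    functional_threshold = functional_threshold,
    enriched_threshold = enriched_threshold
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every key of [run_config()] may appear in the file; `template`,
#' `error_model` and `cleaning` are nested maps with the corresponding
#' constructor arguments. Unknown keys raise an error naming them.
#'
#' @param path YAML path.
#' @param outdir Optional override of the file's `outdir`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  x <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "template", "n_pams", "n_active",
             "edit_prob", "rounds", "unedited_survival",
             "background_escape", "bottleneck_size", "mode", "n_reads",
             "error_model", "cleaning", "max_anchor_mm",
             "functional_threshold", "enriched_threshold")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$template)) x$template <- do.call(amplicon_template,
                                                  x$template)
  if (!is.null(x$error_model)) x$error_model <- do.call(error_model,
                                                        x$error_model)
  if (!is.null(x$cleaning)) x$cleaning <- do.call(cleaning_params,
                                                  x$cleaning)
  if (!is.null(x$edit_prob) && length(x$edit_prob) > 1L)
    x$edit_prob <- unlist(x$edit_prob)
  if (!is.null(outdir)) x$outdir <- outdir
  if (is.null(x$outdir)) stop("config must provide outdir", call. = FALSE)
  do.call(run_config, x)
}

PIPELINE_STAGES <- c("simulate", "process", "stats", "report")

#' Run the end-to-end screen pipeline
#'
#' Executes the requested stages in order:
#' * `simulate` — run the multi-round screen and sequence the initial and
#'   final populations into FASTQ (with truth sidecars);
#' * `process` — classify both FASTQ sets into per-PAM tallies;
#' * `stats` — compute the per-PAM statistics table;
#' * `report` — write tables, figures and run metadata.
#'
#' Runs are idempotent for a fixed config and seed; every artifact is listed
#' with its MD5 checksum in `manifest.json`.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "process", "stats", "report")`.
#' @return Invisibly, a list with `manifest` (data.frame `file, md5`) and
#'   the in-memory `trajectory`, `tallies` and `stats` for the stages that
#'   ran.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(config$outdir, "run_config.yaml"),
    fq_initial = file.path(config$outdir, "initial.fastq.gz"),
    fq_enriched = file.path(config$outdir, "enriched.fastq.gz"),
    trajectory = file.path(config$outdir, "trajectory.tsv"),
    tally_initial = file.path(config$outdir, "tally_initial.tsv"),
    tally_enriched = file.path(config$outdir, "tally_enriched.tsv")
  )
  .write_resolved_config(config, paths$config)
  out <- list()

  if ("simulate" %in% stages) {
    params <- screen_params(edit_prob = config$edit_prob,
                            background_escape = config$background_escape,
                            unedited_survival = config$unedited_survival,
                            bottleneck_size = config$bottleneck_size,
                            rounds = config$rounds, mode = config$mode,
                            seed = config$seed)
    total <- if (config$mode == "stochastic") config$bottleneck_size else 1
    init <- init_population(
      stats::setNames(rep(1, length(config$library_pams)),
                      config$library_pams),
      edited_fraction = 0, total = total)
    traj <- run_screen(init, params)
    out$trajectory <- traj
    write_trajectory(traj, paths$trajectory)
    rs_init <- couple_to_reads(traj$populations[[1]], config$template,
                               config$n_reads, config$error_model,
                               seed = config$seed + 1L)
    rs_enr <- couple_to_reads(traj$populations[[config$rounds + 1L]],
                              config$template, config$n_reads,
                              config$error_model,
                              seed = config$seed + 2L)
    write_read_set(rs_init, paths$fq_initial)
    write_read_set(rs_enr, paths$fq_enriched)
  }

  if ("process" %in% stages) {
    for (lib in c("initial", "enriched")) {
      fq <- paths[[paste0("fq_", lib)]]
      if (!file.exists(fq))
        stop("stage 'process' needs FASTQ from 'simulate': missing ", fq,
             call. = FALSE)
      tally <- process_fastq(fq, config$template, config$cleaning,
                             config$max_anchor_mm)
      out$tallies[[lib]] <- tally
      write_tally(tally, paths[[paste0("tally_", lib)]])
    }
  }

  if ("stats" %in% stages) {
    if (is.null(out$tallies)) {
      if (!file.exists(paths$tally_initial))
        stop("stage 'stats' needs tallies from 'process'", call. = FALSE)
      out$tallies <- list(initial = read_tally(paths$tally_initial),
                          enriched = read_tally(paths$tally_enriched))
    }
    out$stats <- pam_stats(out$tallies$initial, out$tallies$enriched,
                           config$functional_threshold,
                           config$enriched_threshold)
  }

  if ("report" %in% stages) {
    if (is.null(out$stats))
      stop("stage 'report' needs the statistics table from 'stats'",
           call. = FALSE)
    write_reports(out$stats, config$outdir, seed = config$seed,
                  config = .config_as_list(config))
  }

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}

.config_as_list <- function(config) {
  tpl <- config$template
  list(
    outdir = config$outdir, seed = config$seed,
    template = list(name = tpl$name, anchor5 = tpl$anchor5,
                    anchor3 = tpl$anchor3, pam_length = tpl$pam_length,
                    codon_offset = tpl$codon_slot[1] - tpl$pam_slot[2],
                    reference_codon = tpl$reference_codon,
                    pam_report_strand = tpl$pam_report_strand),
    n_active = sum(config$edit_prob > 0),
    edit_prob = as.list(config$edit_prob[config$edit_prob > 0]),
    rounds = config$rounds,
    unedited_survival = config$unedited_survival,
    background_escape = config$background_escape,
    bottleneck_size = config$bottleneck_size, mode = config$mode,
    n_reads = config$n_reads,
    error_model = unclass(config$error_model),
    cleaning = unclass(config$cleaning),
    max_anchor_mm = config$max_anchor_mm,
    functional_threshold = config$functional_threshold,
    enriched_threshold = config$enriched_threshold
  )
}

.write_resolved_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}
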