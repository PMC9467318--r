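#' Configuration for an end-to-end pipeline run
#'
#' @param input_mode One of `"scores"` (a long-format score table),
#'   `"events"` (a trial manifest pointing at event/click/layout files) or
#'   `"raw"` (a manifest pointing at raw gaze-sample files).
#' @param input Path to the score table (`"scores"`) or manifest TSV
#'   (`"events"`/`"raw"`). Manifest columns: `subject`, `test_type`,
#'   `instruction`, `start_t`, `end_t`, `clicks_file`, `layout_file` and
#'   `events_file` or `gaze_file`; file paths are resolved relative to the
#'   manifest.
#' @param out_dir Output directory (created if missing).
#' @param geometry A [screen_geometry()].
#' @param detection A [detection_params()].
#' @param priors A [bf_prior_spec()].
#' @param bootstrap_b Bootstrap replicates for the dominance R-squared
#'   intervals.
#' @param dvs Test scores to model; defaults to all eight.
#' @param include_unassigned Count unassigned fixations in `n_fixations`?
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_mode = c("scores", "events", "raw"), input,
                       out_dir = "tmt_out", geometry = screen_geometry(),
                       detection = detection_params(),
                       priors = bf_prior_spec(), bootstrap_b = 1000,
                       dvs = .score_measures(), include_unassigned = TRUE,
                       seed = 1) {
  input_mode <- match.arg(input_mode)
  if (!file.exists(input)) stop("input file does not exist: ", input)
  structure(
    list(input_mode = input_mode, input = input, out_dir = out_dir,
         geometry = geometry, detection = detection, priors = priors,
         bootstrap_b = bootstrap_b, dvs = dvs,
         include_unassigned = isTRUE(include_unassigned),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `geometry`,
#' `detection` and `priors` are nested maps whose keys are the respective
#' constructor arguments.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading (e.g. `seed = 7`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  base <- dirname(normalizePath(path))
  input <- y$input
  if (!is.null(input) && !file.exists(input)) {
    input <- file.path(base, input)
  }
  args <- list(
    input_mode = y$input_mode %||% "scores",
    input = input,
    out_dir = y$out_dir %||% "tmt_out",
    bootstrap_b = y$bootstrap_b %||% 1000,
    seed = y$seed %||% 1
  )
  if (!is.null(y$dvs)) args$dvs <- y$dvs
  if (!is.null(y$geometry)) {
    args$geometry <- do.call(screen_geometry, y$geometry)
  }
  if (!is.null(y$detection)) {
    args$detection <- do.call(detection_params, y$detection)
  }
  if (!is.null(y$priors)) args$priors <- do.call(bf_prior_spec, y$priors)
  if (!is.null(y$include_unassigned)) {
    args$include_unassigned <- y$include_unassigned
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_manifest_trials <- function(cfg) {
  man <- utils::read.delim(cfg$input, sep = "\t",
                           colClasses = c(subject = "character"))
  base <- dirname(normalizePath(cfg$input))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  layout_cache <- list()
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    lf <- resolve(man$layout_file[i])
    if (is.null(layout_cache[[lf]])) {
      layout_cache[[lf]] <- read_layout(lf, cfg$geometry)
    }
    layout <- layout_cache[[lf]]
    clicks <- utils::read.delim(resolve(man$clicks_file[i]), sep = "\t")
    if (cfg$input_mode == "raw") {
      samples <- read_gaze(resolve(man$gaze_file[i]))
      ev <- process_gaze(samples, cfg$detection, cfg$geometry)
    } else {
      ev <- read_events(resolve(man$events_file[i]))
      ev$fixations <- merge_fixations(ev$fixations, cfg$detection)
      ev$saccades <- .absorb_saccades(ev$saccades, ev$fixations)
    }
    trials[[i]] <- trial_record(
      man$subject[i], man$test_type[i], man$instruction[i],
      man$start_t[i], man$end_t[i], ev$fixations, ev$saccades,
      clicks, layout)
  }
  trials
}

#' Run the full analysis pipeline
#'
#' From the configured input (raw gaze, pre-detected events, or a score
#' table) to (1) the aggregated score table, (2) the mixed-model summary
#' for every requested test score with its standard log-transform flag,
#' (3) the dominance table per score x test half, and (4) a run log with
#' the seed and all resolved parameters. Identical configuration and seed
#' give byte-identical numeric outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `scores`, `lmm`, `dominance` and the
#'   output file `paths`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(sprintf("trailgaze run, seed %d, input_mode %s",
                         cfg$seed, cfg$input_mode),
                 sprintf("input: %s", cfg$input))
  stage <- function(msg, t_prev) {
    t_now <- proc.time()[["elapsed"]]
    log_lines <<- c(log_lines, sprintf("[%6.2fs] %s", t_now - t0, msg))
    t_now
  }

  scores <- switch(
    cfg$input_mode,
    scores = read_scores(cfg$input),
    {
      trials <- .read_manifest_trials(cfg)
      score_trials(trials, include_unassigned = cfg$include_unassigned)
    }
  )
  stage(sprintf("scored/loaded %d trial rows", nrow(scores)))
  scores <- aggregate_scores(scores)
  stage(sprintf("aggregated to %d subject x cell rows", nrow(scores)))

  specs <- tmt_model_specs()[cfg$dvs]
  lmm <- lmm_report(scores, specs)
  for (dv in cfg$dvs) {
    n_obs <- lmm$n_obs[lmm$dv == dv][1]
    dropped <- nrow(scores) - n_obs
    if (dropped > 0) {
      log_lines <- c(log_lines,
                     sprintf("warning: %d observations dropped for %s",
                             dropped, dv))
    }
  }
  stage(sprintf("fitted %d mixed models", length(cfg$dvs)))

  dom <- dominance_report(scores, dvs = cfg$dvs, priors = cfg$priors,
                          B = cfg$bootstrap_b, seed = cfg$seed)
  stage(sprintf("dominance analysis for %d score x half cells", nrow(dom)))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    scores = file.path(cfg$out_dir, "scores.tsv"),
    lmm = file.path(cfg$out_dir, "lmm_summary.tsv"),
    dominance = file.path(cfg$out_dir, "dominance.tsv"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  write_scores(scores, paths$scores)
  utils::write.table(lmm, paths$lmm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dom, paths$dominance, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("priors: rscale_fixed %g, rscale_random %g",
                         cfg$priors$rscale_fixed, cfg$priors$rscale_random),
                 sprintf("bootstrap B: %d", cfg$bootstrap_b),
                 sprintf("detection: vel %g deg/s, acc %g deg/s^2, merge %g deg",
                         cfg$detection$vel_thresh, cfg$detection$acc_thresh,
                         cfg$detection$merge_dist))
  writeLines(log_lines, paths$log)
  invisible(list(scores = scores, lmm = lmm, dominance = dom,
                 paths = paths))
}

#' Generate a packaged test dataset
#'
#' Deterministic synthetic fixtures with ground-truth sidecars, in the
#' exact text formats the pipeline reads.
#'
#' `"score-level"` writes a 58-subject score table drawn from the
#' reference score-level generator ([tmt_reference_params()]), a
#' `truth.yaml` with the generating parameters, and a ready-to-run
#' `config.yaml`. `"event-level"` writes a small event-level study
#' (8-target training layouts) as manifest + per-trial event and click
#' tables, a ground-truth fixation-role sidecar, and a `config.yaml`.
#'
#' @param kind `"score-level"` or `"event-level"`.
#' @param seed Master seed; identical seeds give identical fixtures.
#' @param dir Output directory.
#' @param n_subjects Number of subjects (defaults: 58 score-level, 4
#'   event-level).
#' @return The directory path, invisibly.
#' @export
make_fixture <- function(kind = c("score-level", "event-level"), seed = 1,
                         dir = tempfile("tmt_fixture_"),
                         n_subjects = NULL) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "score-level") {
    n_subjects <- n_subjects %||% 58
    tbl <- simulate_score_table(n_subjects, seed = seed)
    write_scores(tbl, file.path(dir, "scores.tsv"))
    yaml::write_yaml(
      list(generator = "simulate_score_table", seed = seed,
           n_subjects = n_subjects, params = tmt_reference_params()),
      file.path(dir, "truth.yaml"))
    yaml::write_yaml(
      list(input_mode = "scores", input = "scores.tsv",
           out_dir = "out", seed = seed, bootstrap_b = 200),
      file.path(dir, "config.yaml"))
  } else {
    n_subjects <- n_subjects %||% 4
    sim <- simulate_study(n_subjects,
                          cfg = layout_config(n_targets = 8),
                          seed = seed)
    write_layout(sim$layouts$A, file.path(dir, "layout_A.tsv"))
    write_layout(sim$layouts$B, file.path(dir, "layout_B.tsv"))
    man <- list()
    for (i in seq_along(sim$trials)) {
      tr <- sim$trials[[i]]
      stem <- sprintf("%s_%s_%s", tr$subject, tr$test_type,
                      tr$instruction)
      ev <- structure(list(fixations = tr$fixations,
                           saccades = tr$saccades,
                           blinks = .empty_events()$blinks),
                      class = "gaze_events")
      write_events(ev, file.path(dir, paste0(stem, "_events.tsv")))
      utils::write.table(tr$clicks,
                         file.path(dir, paste0(stem, "_clicks.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      man[[i]] <- data.frame(
        subject = tr$subject, test_type = tr$test_type,
        instruction = tr$instruction, start_t = tr$start_t,
        end_t = tr$end_t,
        events_file = paste0(stem, "_events.tsv"),
        clicks_file = paste0(stem, "_clicks.tsv"),
        layout_file = paste0("layout_", tr$test_type, ".tsv"))
    }
    utils::write.table(do.call(rbind, man), file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(input_mode = "events", input = "manifest.tsv",
           out_dir = "out", seed = seed, bootstrap_b = 200),
      file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
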