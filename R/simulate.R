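# All randomness flows from explicit `seed` arguments. Top-level generators
# run under .with_seed() (caller RNG state untouched); multi-unit generators
# derive one sub-seed per unit with .split_seed() so units are independent
# and individually reproducible.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic seed splitting: sub-seed i of a master seed, kept within
# 32-bit integer range.
.split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483629)
}

# Bivariate normal scatter with radial truncation at trunc*sd, so a draw
# with sd <= 0.5 deg can never leave the 1.625 deg AOI radius of its own
# target nor come closer to a neighbouring target (at the default minimum
# separation) than to its own.
.rnorm2_trunc <- function(sd, trunc = 2.5) {
  if (sd <= 0) return(c(0, 0))
  repeat {
    v <- stats::rnorm(2, 0, sd)
    if (sqrt(sum(v^2)) <= trunc * sd) return(v)
  }
}

#' Layout generator configuration
#'
#' Targets are placed by picking distinct fields of a `grid_nx` x `grid_ny`
#' grid spanning the screen and jittering each target uniformly around its
#' field center; whole layouts are rejection-sampled until all pairwise
#' target distances reach `min_sep`.
#'
#' @param n_targets Number of targets: 25 for an experimental trial, 8 for
#'   a training trial.
#' @param jitter Maximum displacement from the field center, per axis
#'   (deg).
#' @param min_sep Minimum pairwise target distance (deg); must be at least
#'   the 1.35 deg target circle so hit zones cannot overlap. The default
#'   2.6 additionally keeps guiding/searching classification unambiguous at
#'   the generator's truncated fixation scatter.
#' @param grid_nx,grid_ny Grid dimensions.
#' @param max_tries Rejection-sampling budget before a layout error.
#' @param geom A [screen_geometry()].
#' @return An object of class `layout_config`.
#' @export
layout_config <- function(n_targets = 25, jitter = 0.8, min_sep = 2.6,
                          grid_nx = 5, grid_ny = 5, max_tries = 200,
                          geom = screen_geometry()) {
  if (n_targets < 1 || n_targets > grid_nx * grid_ny) {
    stop("n_targets must be between 1 and the number of grid fields")
  }
  if (min_sep < 1.35) stop("min_sep must be at least 1.35 deg")
  if (jitter < 0) stop("jitter must be non-negative")
  structure(
    list(n_targets = n_targets, jitter = jitter, min_sep = min_sep,
         grid_nx = grid_nx, grid_ny = grid_ny, max_tries = max_tries,
         geom = geom),
    class = "layout_config"
  )
}

#' Generate a random target layout
#'
#' @param version `"A"` or `"B"` (decides the label sequence).
#' @param cfg A [layout_config()].
#' @param seed Integer seed; identical seeds give identical layouts.
#' @return A [target_layout()].
#' @export
generate_layout <- function(version = c("A", "B"), cfg = layout_config(),
                            seed = NULL) {
  version <- match.arg(version)
  .with_seed(seed, {
    geom <- cfg$geom
    fx <- (seq_len(cfg$grid_nx) - 0.5) / cfg$grid_nx * geom$res_x_px
    fy <- (seq_len(cfg$grid_ny) - 0.5) / cfg$grid_ny * geom$res_y_px
    fields <- as.matrix(expand.grid(x = fx, y = fy))
    for (try in seq_len(cfg$max_tries)) {
      pick <- sample(nrow(fields), cfg$n_targets)
      jit_deg <- matrix(stats::runif(2 * cfg$n_targets, -cfg$jitter,
                                     cfg$jitter), ncol = 2)
      centers_deg <- px_to_deg(fields[pick, , drop = FALSE], geom) + jit_deg
      centers_px <- deg_to_px(centers_deg, geom)
      d <- stats::dist(centers_deg)
      if (cfg$n_targets < 2 || min(d) >= cfg$min_sep) {
        return(target_layout(version, centers_px,
                             labels = tmt_labels(version, cfg$n_targets),
                             geom = geom))
      }
    }
    stop("layout error: min_sep unsatisfiable within max_tries rejections")
  })
}

#' Behavioural parameters for the event-level trial generator
#'
#' Encodes the speed-accuracy trade-off: under speed instructions fewer
#' searching fixations (`search_mult_speed` <= 1) and shorter eye-hand
#' spans, but less precise clicking (larger `click_sd_deg_speed`), hence
#' more misses and re-clicks. TMT-B multiplies the searching rate
#' (`search_mult_b` >= 1). Per-subject intercepts are log-normal
#' multipliers drawn by [draw_subject()].
#'
#' @param fix_dur_meanlog,fix_dur_sdlog Log-normal fixation duration (ms);
#'   defaults center near 160 ms.
#' @param subj_sd_fixdur Subject SD of the fixation-duration meanlog.
#' @param search_rate Mean searching fixations per target (accuracy, TMT-A
#'   baseline); counts are Poisson.
#' @param search_mult_speed,search_mult_b Condition multipliers on the
#'   searching rate (`search_mult_speed` must not exceed 1, the accuracy
#'   baseline).
#' @param subj_sd_search Subject SD of the log searching rate.
#' @param span_mean_s Mean eye-hand span (s) under accuracy instructions.
#' @param span_mult_speed Speed-condition multiplier on the span (< 1).
#' @param span_sdlog Log-normal span dispersion.
#' @param subj_sd_span Subject SD of the log span.
#' @param click_sd_deg_accuracy,click_sd_deg_speed Click scatter around the
#'   target center (deg SD) per instruction.
#' @param scatter_sd_deg Fixation landing scatter (deg SD, radially
#'   truncated at `scatter_trunc` SDs).
#' @param scatter_trunc Truncation radius in SD units.
#' @param saccade_gap_ms Nominal inter-fixation gap (ms).
#' @param reclick_delay_ms Delay before a corrective click after a miss.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(fix_dur_meanlog = log(160),
                            fix_dur_sdlog = 0.25,
                            subj_sd_fixdur = 0.12,
                            search_rate = 3,
                            search_mult_speed = 0.65,
                            search_mult_b = 1.4,
                            subj_sd_search = 0.30,
                            span_mean_s = 1.0,
                            span_mult_speed = 0.60,
                            span_sdlog = 0.30,
                            subj_sd_span = 0.20,
                            click_sd_deg_accuracy = 0.20,
                            click_sd_deg_speed = 0.45,
                            scatter_sd_deg = 0.30,
                            scatter_trunc = 2.5,
                            saccade_gap_ms = 30,
                            reclick_delay_ms = 300) {
  p <- as.list(environment())
  pos <- c("fix_dur_sdlog", "search_rate", "span_mean_s", "span_sdlog",
           "saccade_gap_ms", "reclick_delay_ms", "scatter_trunc")
  if (any(unlist(p[pos]) <= 0)) {
    stop("rate/duration parameters must be strictly positive")
  }
  if (search_mult_speed > 1) {
    stop("search_mult_speed must not exceed the accuracy baseline of 1")
  }
  structure(p, class = "behavior_params")
}

#' Draw per-subject behavioural intercepts
#'
#' @param params A [behavior_params()].
#' @param seed Optional seed.
#' @return List with `fix_dur_meanlog`, `search_rate`, `span_mean_s` for
#'   one subject.
#' @export
draw_subject <- function(params = behavior_params(), seed = NULL) {
  .with_seed(seed, list(
    fix_dur_meanlog = params$fix_dur_meanlog +
      stats::rnorm(1, 0, params$subj_sd_fixdur),
    search_rate = params$search_rate *
      exp(stats::rnorm(1, 0, params$subj_sd_search)),
    span_mean_s = params$span_mean_s *
      exp(stats::rnorm(1, 0, params$subj_sd_span))
  ))
}

#' Simulate one event-level TMT trial
#'
#' Generates, target by target, a run of searching fixations on other
#' targets (Poisson count, condition-scaled), then one guiding fixation on
#' the current target, then a click after an eye-hand-span delay; click
#' positions scatter around the target center with condition-dependent
#' precision and misses (outside the 1.35 deg circle) trigger re-clicks.
#' A guiding fixation never begins before its target becomes current (the
#' preceding target's hit), matching the scoring definition. Ground-truth
#' fixation roles are attached for validation.
#'
#' @param layout A [target_layout()].
#' @param condition List with `test_type` (`"A"`/`"B"`) and `instruction`
#'   (`"accuracy"`/`"speed"`).
#' @param subject Per-subject intercepts from [draw_subject()].
#' @param params A [behavior_params()].
#' @param subject_id Subject identifier stored in the record.
#' @param start_t Trial start time (ms).
#' @param seed Optional seed.
#' @return A [trial_record()] with an extra element `truth`: a data frame
#'   of simulated fixation roles (`role`, `target`).
#' @export
simulate_trial <- function(layout, condition, subject = draw_subject(params),
                           params = behavior_params(), subject_id = "s01",
                           start_t = 0, seed = NULL) {
  stopifnot(inherits(layout, "tmt_layout"),
            inherits(params, "behavior_params"))
  test_type <- match.arg(condition$test_type, c("A", "B"))
  instruction <- match.arg(condition$instruction, c("accuracy", "speed"))
  .with_seed(seed, {
    n <- nrow(layout$targets)
    centers <- layout$centers_deg
    search_mult <- (if (instruction == "speed") params$search_mult_speed else 1) *
      (if (test_type == "B") params$search_mult_b else 1)
    span_mult <- if (instruction == "speed") params$span_mult_speed else 1
    click_sd <- if (instruction == "accuracy") {
      params$click_sd_deg_accuracy
    } else {
      params$click_sd_deg_speed
    }

    fx <- list()
    truth <- list()
    clicks <- list()
    t <- start_t
    prev_target <- NA_integer_
    last_hit <- start_t

    add_fix <- function(target, role, not_before = -Inf) {
      onset <- max(t, not_before) + params$saccade_gap_ms
      dur <- stats::rlnorm(1, subject$fix_dur_meanlog, params$fix_dur_sdlog)
      centroid <- centers[target, ] +
        .rnorm2_trunc(params$scatter_sd_deg, params$scatter_trunc)
      fx[[length(fx) + 1L]] <<- data.frame(
        onset = onset, offset = onset + dur, duration = dur,
        x_deg = centroid[1], y_deg = centroid[2])
      truth[[length(truth) + 1L]] <<- data.frame(
        role = role, target = target,
        target_label = layout$targets$label[target])
      t <<- onset + dur
      prev_target <<- target
      onset
    }

    for (k in seq_len(n)) {
      n_search <- stats::rpois(1, subject$search_rate * search_mult)
      # Exclude the current target (its fixation is the guiding one) and
      # the previous target, which may still be current while the hand
      # lags: a searching fixation must classify as searching.
      others <- setdiff(seq_len(n), c(k, k - 1L))
      if (!length(others)) n_search <- 0L
      for (j in seq_len(n_search)) {
        pool <- setdiff(others, prev_target)
        if (!length(pool)) pool <- others
        tg <- pool[sample.int(length(pool), 1)]
        add_fix(tg, "searching")
      }
      guide_onset <- add_fix(k, "guiding", not_before = last_hit)

      span <- stats::rlnorm(1, log(subject$span_mean_s * span_mult),
                            params$span_sdlog)
      click_t <- guide_onset + span * 1000
      repeat {
        pos_deg <- centers[k, ] + stats::rnorm(2, 0, click_sd)
        pos_px <- deg_to_px(pos_deg, layout$geom)
        hit <- angular_distance(pos_deg, centers[k, ]) <=
          layout$circle_diameter / 2
        clicks[[length(clicks) + 1L]] <- data.frame(
          t_ms = click_t, x_px = pos_px[1], y_px = pos_px[2],
          hit = hit, target_index = k)
        if (hit) break
        click_t <- click_t + params$reclick_delay_ms
      }
      last_hit <- click_t
    }

    fixations <- do.call(rbind, fx)
    clicks <- do.call(rbind, clicks)
    truth <- do.call(rbind, truth)
    end_t <- last_hit

    # Gaze may still be in flight when the final hit lands; clamp events to
    # the trial window.
    fixations$offset <- pmin(fixations$offset, end_t)
    fixations$duration <- fixations$offset - fixations$onset
    keep <- fixations$duration > 0
    fixations <- fixations[keep, , drop = FALSE]
    truth <- truth[keep, , drop = FALSE]
    rownames(fixations) <- rownames(truth) <- NULL

    # Nominal saccades between consecutive fixation centroids at a fixed
    # 300 deg/s; long waits (eyes dwelling) stay outside the saccade.
    saccades <- .nominal_saccades(fixations)

    trial <- trial_record(subject_id, test_type, instruction, start_t,
                          end_t, fixations, saccades, clicks, layout)
    trial$truth <- truth
    trial
  })
}

.nominal_saccades <- function(fixations, peak_vel = 300) {
  nf <- nrow(fixations)
  if (nf < 2) return(.empty_events()$saccades)
  amp <- sqrt(diff(fixations$x_deg)^2 + diff(fixations$y_deg)^2)
  gap_lo <- fixations$offset[-nf]
  gap_hi <- fixations$onset[-1]
  dur <- pmin(amp / peak_vel * 1000, gap_hi - gap_lo)
  data.frame(onset = gap_hi - dur, offset = gap_hi, duration = dur,
             amplitude = amp, peak_velocity = peak_vel)
}

#' Render a trial's events as a raw gaze-sample stream
#'
#' Inverse of event detection, for pipeline self-consistency tests: gaze
#' holds each fixation centroid for its duration and moves between
#' centroids along a linear ramp at a fixed peak velocity (default
#' 300 deg/s, comfortably above the 30 deg/s detection threshold), so
#' [detect_events()] recovers the simulated fixation sequence.
#'
#' @param trial A [simulate_trial()] result.
#' @param rate_hz Sampling rate (default 1000 Hz).
#' @param peak_vel Saccade velocity for the ramps (deg/s).
#' @return A gaze-sample data frame (`t_ms`, `x_px`, `y_px`, `valid`).
#' @export
render_gaze <- function(trial, rate_hz = 1000, peak_vel = 300) {
  stopifnot(inherits(trial, "tmt_trial"))
  fx <- trial$fixations
  if (!nrow(fx)) stop("trial has no fixations to render")
  dt <- 1000 / rate_hz
  t <- seq(fx$onset[1], fx$offset[nrow(fx)], by = dt)
  x <- numeric(length(t))
  y <- numeric(length(t))
  nf <- nrow(fx)
  for (i in seq_len(nf)) {
    hold_hi <- if (i < nf) fx$onset[i + 1] else fx$offset[nf] + dt
    amp <- if (i < nf) {
      angular_distance(c(fx$x_deg[i], fx$y_deg[i]),
                       c(fx$x_deg[i + 1], fx$y_deg[i + 1]))
    } else 0
    ramp_dur <- if (i < nf) {
      min(amp / peak_vel * 1000, fx$onset[i + 1] - fx$offset[i])
    } else 0
    ramp_start <- hold_hi - ramp_dur
    sel_hold <- t >= fx$onset[i] & t < ramp_start
    x[sel_hold] <- fx$x_deg[i]
    y[sel_hold] <- fx$y_deg[i]
    if (i < nf && ramp_dur > 0) {
      sel_ramp <- t >= ramp_start & t < hold_hi
      frac <- (t[sel_ramp] - ramp_start) / ramp_dur
      x[sel_ramp] <- fx$x_deg[i] + frac * (fx$x_deg[i + 1] - fx$x_deg[i])
      y[sel_ramp] <- fx$y_deg[i] + frac * (fx$y_deg[i + 1] - fx$y_deg[i])
    }
  }
  px <- deg_to_px(cbind(x, y), trial$layout$geom)
  data.frame(t_ms = t, x_px = px[, 1], y_px = px[, 2], valid = TRUE)
}

#' Simulate a full event-level study
#'
#' One layout per test version (shared by all subjects), one trial per
#' subject x test_type x instruction cell.
#'
#' @param n_subjects Number of subjects.
#' @param params A [behavior_params()].
#' @param cfg A [layout_config()] (applied to both versions).
#' @param seed Master seed; layouts, subjects and trials get split
#'   sub-seeds.
#' @return List with `trials` (list of [trial_record()]s), `layouts`
#'   (versions A and B), `subjects` (drawn intercepts) and `truth` (row-bound
#'   ground-truth fixation roles with subject/condition columns).
#' @export
simulate_study <- function(n_subjects = 4, params = behavior_params(),
                           cfg = layout_config(), seed = 1) {
  layouts <- list(A = generate_layout("A", cfg, seed = .split_seed(seed, 1)),
                  B = generate_layout("B", cfg, seed = .split_seed(seed, 2)))
  ids <- sprintf("s%02d", seq_len(n_subjects))
  trials <- list()
  truth <- list()
  subjects <- list()
  cells <- expand.grid(test_type = c("A", "B"),
                       instruction = c("accuracy", "speed"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_subjects)) {
    subjects[[ids[i]]] <- draw_subject(params,
                                       seed = .split_seed(seed, 100 + i))
    for (j in seq_len(nrow(cells))) {
      tr <- simulate_trial(
        layouts[[cells$test_type[j]]],
        condition = list(test_type = cells$test_type[j],
                         instruction = cells$instruction[j]),
        subject = subjects[[ids[i]]], params = params,
        subject_id = ids[i],
        seed = .split_seed(seed, 1000 + 10 * i + j))
      trials[[length(trials) + 1L]] <- tr
      tt <- tr$truth
      tt$subject <- ids[i]
      tt$test_type <- cells$test_type[j]
      tt$instruction <- cells$instruction[j]
      tt$fix_index <- seq_len(nrow(tt))
      truth[[length(truth) + 1L]] <- tt
    }
  }
  list(trials = trials, layouts = layouts, subjects = subjects,
       truth = do.call(rbind, truth))
}

#' Score-level simulation configuration
#'
#' Direct generator for the random-intercept model the analysis assumes:
#' `y_ij = X beta + u_j + e_ij` with `u_j ~ N(0, sd_subject^2)`,
#' `e_ij ~ N(0, sd_resid^2)`, dummy coding with reference levels TMT-A and
#' accuracy, one observation per subject and design cell.
#'
#' @param betas Length-4 fixed effects on the model scale: intercept,
#'   test type (B vs A), instruction (speed vs accuracy), interaction.
#' @param sd_subject Random-intercept SD.
#' @param sd_resid Residual SD.
#' @param n_subjects Number of subjects (>= 2).
#' @param response Name of the generated response column.
#' @param log_response If `TRUE`, `betas` are on the natural-log scale and
#'   the stored response is exponentiated (so fitting with
#'   `log_transform = TRUE` recovers them).
#' @return An object of class `score_sim_config`.
#' @export
score_sim_config <- function(betas = c(72.55, 22.97, -28.18, 14.20),
                             sd_subject = 17.22, sd_resid = 20.9,
                             n_subjects = 58, response = "value",
                             log_response = FALSE) {
  if (length(betas) != 4) stop("betas must have length 4")
  if (sd_subject < 0 || sd_resid < 0) stop("SDs must be non-negative")
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  structure(
    list(betas = betas, sd_subject = sd_subject, sd_resid = sd_resid,
         n_subjects = as.integer(n_subjects), response = response,
         log_response = isTRUE(log_response)),
    class = "score_sim_config"
  )
}

#' Simulate a score-level dataset
#'
#' @param cfg A [score_sim_config()].
#' @param seed Optional seed; identical seeds give identical tables.
#' @return Long-format data frame with columns `subject`, `test_type`,
#'   `instruction` and the response named in `cfg` (exactly
#'   `n_subjects * 4` rows).
#' @export
simulate_scores <- function(cfg = score_sim_config(), seed = NULL) {
  .with_seed(seed, {
    ids <- sprintf("s%02d", seq_len(cfg$n_subjects))
    df <- expand.grid(instruction = c("accuracy", "speed"),
                      test_type = c("A", "B"), subject = ids,
                      stringsAsFactors = FALSE)
    df <- df[, c("subject", "test_type", "instruction")]
    tt <- as.numeric(df$test_type == "B")
    ins <- as.numeric(df$instruction == "speed")
    mu <- cfg$betas[1] + cfg$betas[2] * tt + cfg$betas[3] * ins +
      cfg$betas[4] * tt * ins
    u <- stats::rnorm(cfg$n_subjects, 0, cfg$sd_subject)
    y <- mu + u[match(df$subject, ids)] +
      stats::rnorm(nrow(df), 0, cfg$sd_resid)
    df[[cfg$response]] <- if (cfg$log_response) exp(y) else y
    rownames(df) <- NULL
    df
  })
}

#' Reference generator parameters for the eight test scores
#'
#' Default score-level generator settings, one per test score, on realistic
#' scales for a computerized TMT in healthy adults: fixed effects
#' (intercept, test type, instruction, interaction), subject-intercept SD,
#' residual SD, and whether the score is modelled on the natural-log scale
#' (fixation counts, searching-fixation counts, eye-hand span and scanpath
#' length are right-skewed and modelled on the log scale; their slopes and
#' SDs are then unit-free).
#'
#' @return Named list (one element per score) of lists with `betas`,
#'   `sd_subject`, `sd_resid`, `log`.
#' @export
tmt_reference_params <- function() {
  list(
    trial_duration = list(betas = c(72.55, 22.97, -28.18, 14.20),
                          sd_subject = 17.22, sd_resid = 20.9, log = FALSE),
    mean_fixation_duration = list(betas = c(160.80, 3.40, 2.22, -1.90),
                                  sd_subject = 19.85, sd_resid = 6.20,
                                  log = FALSE),
    mean_saccade_amplitude = list(betas = c(4.62, -0.18, -0.21, 0.45),
                                  sd_subject = 0.50, sd_resid = 0.344,
                                  log = FALSE),
    n_fixations = list(betas = c(5.54, 0.25, -0.33, 0.30),
                       sd_subject = 0.26, sd_resid = 0.206, log = TRUE),
    n_guiding = list(betas = c(53.73, -1.27, -2.58, 1.83),
                     sd_subject = 10.74, sd_resid = 8.66, log = FALSE),
    n_searching = list(betas = c(4.31, 0.34, -0.43, 0.26),
                       sd_subject = 0.30, sd_resid = 0.302, log = TRUE),
    mean_eye_hand_span = list(betas = c(0.572, 0.05, -0.49, 0.27),
                              sd_subject = 0.23, sd_resid = 0.247,
                              log = TRUE),
    scanpath_length = list(betas = c(4.83, 0.31, -0.395, 0.35),
                           sd_subject = 0.27, sd_resid = 0.247, log = TRUE)
  )
}

#' Simulate a score table for all eight test scores
#'
#' One [simulate_scores()] draw per score (independent subject intercepts
#' per score), merged into a wide table that matches the scoring module's
#' output format.
#'
#' @param n_subjects Number of subjects.
#' @param params Reference parameters as in [tmt_reference_params()].
#' @param missing_rate Proportion of cells set to `NA` per score
#'   (independently), emulating incomplete recordings; default 0.
#' @param seed Master seed.
#' @return Data frame with `subject`, `test_type`, `instruction` and the
#'   eight score columns.
#' @export
simulate_score_table <- function(n_subjects = 58,
                                 params = tmt_reference_params(),
                                 missing_rate = 0, seed = 1) {
  out <- NULL
  for (i in seq_along(params)) {
    dv <- names(params)[i]
    p <- params[[i]]
    cfg <- score_sim_config(betas = p$betas, sd_subject = p$sd_subject,
                            sd_resid = p$sd_resid, n_subjects = n_subjects,
                            response = dv, log_response = p$log)
    df <- simulate_scores(cfg, seed = .split_seed(seed, i))
    if (missing_rate > 0) {
      drop <- .with_seed(.split_seed(seed, 100 + i),
                         stats::runif(nrow(df)) < missing_rate)
      df[[dv]][drop] <- NA_real_
    }
    out <- if (is.null(out)) df else cbind(out, df[dv])
  }
  out
}
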