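#' Task configuration
#'
#' Geometry and round structure of the search task. Targets spawn uniformly
#' in a rectangle of +/- `spawn_azimuth_halfwidth` degrees horizontally and
#' +/- `spawn_elevation_halfwidth` degrees vertically around the midsagittal
#' plane; the horizontal spawn extent is deliberately wider than the
#' headset's field of view so the player must explore. Rounds of
#' `targets_per_round` targets are separated by nothing; within a round a
#' new target appears a fixed inter-stimulus interval after the previous
#' one resolved (tagged or expired).
#'
#' @param spawn_azimuth_halfwidth Degrees (default 60).
#' @param spawn_elevation_halfwidth Degrees (default 50).
#' @param fov_horizontal Headset horizontal field of view, degrees
#'   (default 110). Must be smaller than the full spawn width.
#' @param targets_per_round Targets per round (default 30).
#' @param n_rounds Rounds per session (default 10).
#' @param isi Inter-stimulus interval, seconds (default 2).
#' @param starting_level First round's difficulty level (default 1).
#' @param speed_floor_override Optional replacement for the level-1 target
#'   speed (patient task version: 0.1 deg/s). The per-level speed delta
#'   still applies on top of the override at higher levels.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(spawn_azimuth_halfwidth = 60,
                        spawn_elevation_halfwidth = 50,
                        fov_horizontal = 110,
                        targets_per_round = 30L,
                        n_rounds = 10L,
                        isi = 2,
                        starting_level = 1L,
                        speed_floor_override = NULL) {
  if (spawn_azimuth_halfwidth <= 0 || spawn_elevation_halfwidth <= 0 ||
      fov_horizontal <= 0 || isi <= 0) {
    stop("spawn halfwidths, fov and isi must be strictly positive",
         call. = FALSE)
  }
  if (2 * spawn_azimuth_halfwidth <= fov_horizontal) {
    stop("spawn area must exceed the horizontal field of view ",
         "(2 * spawn_azimuth_halfwidth > fov_horizontal)", call. = FALSE)
  }
  if (targets_per_round < 1 || n_rounds < 1) {
    stop("targets_per_round and n_rounds must be positive counts",
         call. = FALSE)
  }
  if (!is.null(speed_floor_override) && speed_floor_override <= 0) {
    stop("speed_floor_override must be strictly positive", call. = FALSE)
  }
  structure(
    list(spawn_azimuth_halfwidth = spawn_azimuth_halfwidth,
         spawn_elevation_halfwidth = spawn_elevation_halfwidth,
         fov_horizontal = fov_horizontal,
         targets_per_round = as.integer(targets_per_round),
         n_rounds = as.integer(n_rounds),
         isi = isi,
         starting_level = as.integer(starting_level),
         speed_floor_override = speed_floor_override),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> spawn +/-%g x +/-%g deg, fov %g deg, %d targets x %d rounds, isi %g s, start level %d%s\n",
    x$spawn_azimuth_halfwidth, x$spawn_elevation_halfwidth,
    x$fov_horizontal, x$targets_per_round, x$n_rounds, x$isi,
    x$starting_level,
    if (is.null(x$speed_floor_override)) "" else
      sprintf(", speed floor %g deg/s", x$speed_floor_override)))
  invisible(x)
}

# Level parameters with the patient-version speed floor applied: the
# override replaces the level-1 speed, the per-level delta applies on top.
effective_params <- function(table, level, config) {
  p <- level_params(table, level)
  if (!is.null(config$speed_floor_override)) {
    p$speed <- config$speed_floor_override +
      (level - 1) * table$change$speed
  }
  p
}

#' Spawn one (unresolved) target
#'
#' Azimuth and elevation are drawn uniformly over the spawn rectangle, the
#' horizontal flight direction is left/right with probability 1/2 each, and
#' speed and lifetime come from the level parameters. Hemispace is left iff
#' azimuth < 0 (an exact 0, probability zero under continuous sampling,
#' counts as right).
#'
#' @param config A [task_config()].
#' @param params [level_params()] of the current level.
#' @param spawn_time Session-clock time of appearance, seconds.
#' @param round_index Round the target belongs to.
#' @return One-row data.frame (an unresolved target event).
#' @export
spawn_target <- function(config, params, spawn_time = 0, round_index = 1L) {
  az <- stats::runif(1, -config$spawn_azimuth_halfwidth,
                     config$spawn_azimuth_halfwidth)
  el <- stats::runif(1, -config$spawn_elevation_halfwidth,
                     config$spawn_elevation_halfwidth)
  dir <- if (stats::runif(1) < 0.5) -1L else 1L
  data.frame(
    round_index = as.integer(round_index),
    level = params$level,
    spawn_time_s = spawn_time,
    azimuth_deg = az,
    elevation_deg = el,
    direction = dir,
    speed_deg_s = params$speed,
    lifetime_s = params$lifetime,
    hemispace = if (az < 0) "left" else "right",
    found = NA,
    search_time_s = NA_real_
  )
}

#' Resolve a target against an agent
#'
#' Applies the agent's response model (see [agent_profile()]): the search
#' time is the deterministic closed form times the left-hemispace penalty
#' times a lognormal noise factor with median 1. The target is found iff
#' the search time does not exceed its lifetime; a missed target carries no
#' search time.
#'
#' @param agent An [agent_profile()].
#' @param target A one-row unresolved target event from [spawn_target()].
#' @return The target event with `found` and `search_time_s` resolved.
#' @export
simulate_target_trial <- function(agent, target) {
  stopifnot(inherits(agent, "agent_profile"), is.data.frame(target),
            nrow(target) == 1L)
  base <- agent$base_latency + abs(target$azimuth_deg) / agent$scan_speed +
    agent$aim_time
  penalty <- if (target$hemispace == "left") {
    1 + agent$bias_gain * agent$lateral_bias
  } else 1
  eps <- if (agent$noise_sigma > 0) {
    exp(stats::rnorm(1, mean = 0, sd = agent$noise_sigma))
  } else 1
  st <- base * penalty * eps
  if (st <= target$lifetime_s) {
    target$found <- TRUE
    target$search_time_s <- st
  } else {
    target$found <- FALSE
    target$search_time_s <- NA_real_
  }
  target
}

#' Simulate one round
#'
#' Spawns `targets_per_round` targets sequentially: each appears one
#' inter-stimulus interval after the previous target resolved (was tagged,
#' or expired at its lifetime).
#'
#' @param agent An [agent_profile()].
#' @param config A [task_config()].
#' @param table A [difficulty_table()].
#' @param level Difficulty level of this round.
#' @param t0 Session-clock time at which the round starts.
#' @param round_index Round number within the session.
#' @return A list of class `round_record`: `level`, `events` (data.frame
#'   of resolved target events), `outcome` (`n_targets`, `n_found`),
#'   `end_time`.
#' @export
run_round <- function(agent, config, table, level, t0 = 0,
                      round_index = 1L) {
  params <- effective_params(table, level, config)
  n <- config$targets_per_round
  az <- stats::runif(n, -config$spawn_azimuth_halfwidth,
                     config$spawn_azimuth_halfwidth)
  el <- stats::runif(n, -config$spawn_elevation_halfwidth,
                     config$spawn_elevation_halfwidth)
  dir <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  hemi <- ifelse(az < 0, "left", "right")
  base <- agent$base_latency + abs(az) / agent$scan_speed + agent$aim_time
  penalty <- ifelse(az < 0, 1 + agent$bias_gain * agent$lateral_bias, 1)
  eps <- if (agent$noise_sigma > 0) {
    exp(stats::rnorm(n, 0, agent$noise_sigma))
  } else rep(1, n)
  st <- base * penalty * eps
  found <- st <= params$lifetime
  dwell <- ifelse(found, st, params$lifetime)
  spawn <- t0 + c(0, cumsum(dwell + config$isi)[-n])
  events <- data.frame(
    round_index = as.integer(round_index),
    level = as.integer(level),
    spawn_time_s = spawn,
    azimuth_deg = az,
    elevation_deg = el,
    direction = as.integer(dir),
    speed_deg_s = params$speed,
    lifetime_s = params$lifetime,
    hemispace = hemi,
    found = found,
    search_time_s = ifelse(found, st, NA_real_)
  )
  structure(
    list(level = as.integer(level), events = events,
         outcome = list(n_targets = n, n_found = sum(found)),
         end_time = t0 + sum(dwell) + n * config$isi),
    class = "round_record"
  )
}

#' Simulate one session
#'
#' Plays `n_rounds` rounds. The first round uses the configured starting
#' level; each later round's level follows the [next_level()] rule applied
#' to the previous round's percent found.
#'
#' @param agent An [agent_profile()].
#' @param config A [task_config()].
#' @param table A [difficulty_table()] (default [default_table()]).
#' @param participant_id Identifier stored in the record and its logs.
#' @param cohort Cohort label.
#' @param seed Optional integer; when given, seeds the session RNG so the
#'   session is reproducible in isolation.
#' @param hand_trace Generate the controller trace (default TRUE).
#' @param metadata Named list stored verbatim (e.g. CBS score, CoC).
#' @return An object of class `session_record`: fields `participant_id`,
#'   `cohort`, `agent`, `config`, `seed`, `rounds` (list of round records),
#'   `events` (all target events, one data.frame), `level_trajectory`,
#'   `hand_trace`, `metadata`.
#' @export
run_session <- function(agent, config, table = default_table(),
                        participant_id = "P_01", cohort = "unspecified",
                        seed = NULL, hand_trace = TRUE,
                        metadata = list()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (config$starting_level < 1 || config$starting_level > table$n_levels) {
    stop("starting_level must be in [1, ", table$n_levels, "]",
         call. = FALSE)
  }
  level <- config$starting_level
  trajectory <- integer(config$n_rounds)
  rounds <- vector("list", config$n_rounds)
  t <- 0
  for (r in seq_len(config$n_rounds)) {
    trajectory[r] <- level
    rec <- run_round(agent, config, table, level, t0 = t, round_index = r)
    rounds[[r]] <- rec
    t <- rec$end_time
    pct <- percent_found(rec$outcome$n_found, rec$outcome$n_targets)
    level <- next_level(table, level, pct)
  }
  events <- do.call(rbind, lapply(rounds, `[[`, "events"))
  rownames(events) <- NULL
  session <- structure(
    list(participant_id = participant_id, cohort = cohort, agent = agent,
         config = config, seed = if (is.null(seed)) NA_integer_ else
           as.integer(seed),
         rounds = rounds, events = events,
         level_trajectory = trajectory, hand_trace = NULL,
         metadata = metadata),
    class = "session_record"
  )
  if (hand_trace) session$hand_trace <- generate_hand_trace(session)
  session
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %s (%s): %d rounds, levels %s, %d/%d targets found\n",
    x$participant_id, x$cohort, length(x$rounds),
    paste(x$level_trajectory, collapse = ","),
    sum(x$events$found), nrow(x$events)))
  invisible(x)
}

#' Generate a controller (hand) trace for a session
#'
#' Emulates the continuously recorded x-y position of the hand-held
#' controller within a 2 m x 2 m workspace centred on the player, sampled
#' at `hz` Hz. For each found target the hand moves from its current
#' position toward the reach point at arm radius 0.5 m in the target's
#' azimuth direction; with lateral bias `lambda`, reaches into the left
#' hemispace are attenuated toward the midline by the factor
#' `(1 - lambda)`, reproducing the rightward compression of movement seen
#' in neglect. Missed targets produce small drift around the current
#' position. Samples carry Gaussian jitter and are clamped to the
#' workspace.
#'
#' @param session A [run_session()] record.
#' @param hz Sampling rate (default 10 Hz).
#' @param arm_radius Reach radius in meters (default 0.5).
#' @param jitter_sd Positional jitter sd in meters (default 0.01).
#' @return A data.frame `(t_s, x_m, y_m)`; empty for a session without
#'   events.
#' @export
generate_hand_trace <- function(session, hz = 10, arm_radius = 0.5,
                                jitter_sd = 0.01) {
  stopifnot(inherits(session, "session_record"))
  ev <- session$events
  empty <- data.frame(t_s = numeric(0), x_m = numeric(0),
                      y_m = numeric(0))
  if (is.null(ev) || nrow(ev) == 0L) return(empty)
  lambda <- session$agent$lateral_bias
  half <- 1 # workspace half-width, meters
  pos <- c(0, 0)
  n_ev <- nrow(ev)
  found <- ev$found %in% TRUE
  dwell <- ifelse(found, ev$search_time_s, ev$lifetime_s)
  counts <- pmax(2L, ceiling(dwell * hz))
  t_all <- x_all <- y_all <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    n <- counts[i]
    t_all[[i]] <- ev$spawn_time_s[i] + seq(0, dwell[i], length.out = n)
    if (found[i]) {
      az <- ev$azimuth_deg[i] * pi / 180
      reach <- c(arm_radius * sin(az), arm_radius * cos(az))
      if (ev$azimuth_deg[i] < 0) reach[1] <- reach[1] * (1 - lambda)
      frac <- seq(0, 1, length.out = n)
      x_all[[i]] <- pos[1] + frac * (reach[1] - pos[1])
      y_all[[i]] <- pos[2] + frac * (reach[2] - pos[2])
      pos <- reach
    } else {
      x_all[[i]] <- rep(pos[1], n)
      y_all[[i]] <- rep(pos[2], n)
    }
  }
  total <- sum(counts)
  xs <- unlist(x_all) + stats::rnorm(total, 0, jitter_sd)
  ys <- unlist(y_all) + stats::rnorm(total, 0, jitter_sd)
  data.frame(t_s = unlist(t_all),
             x_m = pmin(pmax(xs, -half), half),
             y_m = pmin(pmax(ys, -half), half))
}

#' Generate a cohort of simulated sessions
#'
#' Draws one agent per participant from the cohort spec's distributions
#' (scalar fields are used as-is; `c(min, max)` fields are sampled
#' uniformly), applies the spec's task-config overrides, and runs each
#' session on its own RNG substream derived from the master seed, so the
#' whole cohort is reproducible and any single session can be re-run in
#' isolation.
#'
#' @param spec A [cohort_spec()] (or preset, e.g. [neglect_cohort()]).
#' @param seed Master seed (integer).
#' @param table A [difficulty_table()].
#' @param id_prefix Participant-id prefix (default the cohort label).
#' @param hand_trace Generate controller traces (default TRUE; disable
#'   for metrics-only experiments).
#' @return List of [run_session()] records. Specs with a positive lateral
#'   bias additionally simulate a cancellation sheet per participant and
#'   record the drawn `lateral_bias`, the resulting `coc` and `n_marked`
#'   in the session metadata.
#' @export
generate_cohort <- function(spec, seed = 1L, table = default_table(),
                            id_prefix = NULL, hand_trace = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(id_prefix)) id_prefix <- spec$cohort
  set.seed(as.integer(seed))
  session_seeds <- sample.int(.Machine$integer.max - 1L, spec$n)
  draw <- function(x) if (length(x) == 2L) stats::runif(1, x[1], x[2]) else x
  cfg_args <- spec$config_overrides
  cfg_args$starting_level <- spec$starting_level
  config <- do.call(task_config, cfg_args)
  sessions <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    set.seed(session_seeds[i])
    agent <- agent_profile(
      base_latency = draw(spec$base_latency),
      scan_speed = draw(spec$scan_speed),
      aim_time = draw(spec$aim_time),
      noise_sigma = draw(spec$noise_sigma),
      lateral_bias = draw(spec$lateral_bias),
      bias_gain = draw(spec$bias_gain)
    )
    meta <- list(lateral_bias = agent$lateral_bias)
    if (any(spec$lateral_bias > 0)) {
      marks <- simulate_cancellation(agent$lateral_bias)
      meta$coc <- coc(default_sheet(), marks)$coc
      meta$n_marked <- length(marks)
    }
    sessions[[i]] <- run_session(
      agent, config, table,
      participant_id = sprintf("%s_%02d", id_prefix, i),
      cohort = spec$cohort, seed = session_seeds[i],
      hand_trace = hand_trace, metadata = meta)
  }
  sessions
}
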