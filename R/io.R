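# Serialization: one JSON header + events CSV (+ trace CSV) per session.
# Numeric columns are written with fixed formatting so identical runs give
# byte-identical logs: timestamps with 6 decimals, other floats with 17
# significant digits (lossless for doubles).

fmt_time <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

events_to_csv_df <- function(session) {
  ev <- session$events
  data.frame(
    participant_id = session$participant_id,
    cohort = session$cohort,
    round = ev$round_index,
    level = ev$level,
    spawn_time_s = fmt_time(ev$spawn_time_s),
    azimuth_deg = fmt_num(ev$azimuth_deg),
    elevation_deg = fmt_num(ev$elevation_deg),
    direction = ev$direction,
    speed_deg_s = fmt_num(ev$speed_deg_s),
    lifetime_s = fmt_num(ev$lifetime_s),
    hemispace = ev$hemispace,
    found = ev$found,
    search_time_s = fmt_num(ev$search_time_s),
    stringsAsFactors = FALSE
  )
}

#' Write a session to disk
#'
#' Produces three files under `dir`:
#' `<id>_session.json` (header: package version, seed, config, agent,
#' level trajectory, metadata), `<id>_events.csv` (one row per target
#' event) and `<id>_trace.csv` (controller trace, when present). Identical
#' sessions always serialize to byte-identical files.
#'
#' @param session A [run_session()] record.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the header file path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- session$participant_id
  header <- list(
    format = "birdsearch-session",
    package_version = as.character(utils::packageVersion("birdsearch")),
    participant_id = id,
    cohort = session$cohort,
    seed = session$seed,
    config = unclass(session$config),
    agent = unclass(session$agent),
    level_trajectory = session$level_trajectory,
    n_events = nrow(session$events),
    has_trace = !is.null(session$hand_trace) &&
      nrow(session$hand_trace) > 0L,
    metadata = session$metadata
  )
  hpath <- file.path(dir, paste0(id, "_session.json"))
  jsonlite::write_json(header, hpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  utils::write.csv(events_to_csv_df(session),
                   file.path(dir, paste0(id, "_events.csv")),
                   row.names = FALSE, quote = FALSE)
  if (header$has_trace) {
    tr <- data.frame(t_s = fmt_time(session$hand_trace$t_s),
                     x_m = fmt_num(session$hand_trace$x_m),
                     y_m = fmt_num(session$hand_trace$y_m))
    utils::write.csv(tr, file.path(dir, paste0(id, "_trace.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(hpath)
}

#' Read a session back from disk
#'
#' Inverse of [write_session()]. Integer and string fields round-trip
#' exactly; floats round-trip losslessly except timestamps, which are
#' stored with 6-decimal fixed formatting. The participant id in the
#' header must match every event row.
#'
#' @param header_path Path to the `<id>_session.json` header.
#' @return A [run_session()]-shaped `session_record`.
#' @export
read_session <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("session header not found: ", header_path, call. = FALSE)
  }
  header <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  if (is.null(header$format) || header$format != "birdsearch-session") {
    stop("not a session header: ", header_path, call. = FALSE)
  }
  dir <- dirname(header_path)
  id <- header$participant_id
  epath <- file.path(dir, paste0(id, "_events.csv"))
  if (!file.exists(epath)) {
    stop("events file missing for session ", id, ": ", epath,
         call. = FALSE)
  }
  raw <- utils::read.csv(epath, stringsAsFactors = FALSE)
  needed <- c("participant_id", "round", "level", "spawn_time_s",
              "azimuth_deg", "elevation_deg", "direction", "speed_deg_s",
              "lifetime_s", "hemispace", "found", "search_time_s")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0L) {
    stop("malformed events CSV (", epath, "): missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) != header$n_events) {
    stop("events CSV truncated or padded: header records ",
         header$n_events, " events, file has ", nrow(raw), call. = FALSE)
  }
  if (any(raw$participant_id != id)) {
    stop("participant-id mismatch between header ('", id,
         "') and events CSV", call. = FALSE)
  }
  events <- data.frame(
    round_index = as.integer(raw$round),
    level = as.integer(raw$level),
    spawn_time_s = as.numeric(raw$spawn_time_s),
    azimuth_deg = as.numeric(raw$azimuth_deg),
    elevation_deg = as.numeric(raw$elevation_deg),
    direction = as.integer(raw$direction),
    speed_deg_s = as.numeric(raw$speed_deg_s),
    lifetime_s = as.numeric(raw$lifetime_s),
    hemispace = raw$hemispace,
    found = as.logical(raw$found),
    search_time_s = as.numeric(raw$search_time_s)
  )
  trace <- NULL
  tpath <- file.path(dir, paste0(id, "_trace.csv"))
  if (isTRUE(header$has_trace)) {
    if (!file.exists(tpath)) {
      stop("trace file missing for session ", id, call. = FALSE)
    }
    tr <- utils::read.csv(tpath, stringsAsFactors = FALSE)
    trace <- data.frame(t_s = as.numeric(tr$t_s),
                        x_m = as.numeric(tr$x_m),
                        y_m = as.numeric(tr$y_m))
  }
  cfg <- header$config
  config <- task_config(
    spawn_azimuth_halfwidth = cfg$spawn_azimuth_halfwidth,
    spawn_elevation_halfwidth = cfg$spawn_elevation_halfwidth,
    fov_horizontal = cfg$fov_horizontal,
    targets_per_round = cfg$targets_per_round,
    n_rounds = cfg$n_rounds,
    isi = cfg$isi,
    starting_level = cfg$starting_level,
    speed_floor_override = cfg$speed_floor_override
  )
  ag <- header$agent
  agent <- agent_profile(base_latency = ag$base_latency,
                         scan_speed = ag$scan_speed,
                         aim_time = ag$aim_time,
                         noise_sigma = ag$noise_sigma,
                         lateral_bias = ag$lateral_bias,
                         bias_gain = ag$bias_gain)
  rounds <- lapply(sort(unique(events$round_index)), function(r) {
    ev <- events[events$round_index == r, , drop = FALSE]
    rownames(ev) <- NULL
    structure(
      list(level = ev$level[1], events = ev,
           outcome = list(n_targets = nrow(ev), n_found = sum(ev$found)),
           end_time = NA_real_),
      class = "round_record")
  })
  structure(
    list(participant_id = id, cohort = header$cohort, agent = agent,
         config = config,
         seed = if (is.null(header$seed)) NA_integer_ else
           as.integer(header$seed),
         rounds = rounds, events = events,
         level_trajectory = as.integer(header$level_trajectory),
         hand_trace = trace,
         metadata = as.list(header$metadata)),
    class = "session_record"
  )
}

#' Read every session in a directory
#'
#' @param dir Directory containing `*_session.json` headers.
#' @return List of `session_record`s.
#' @export
read_sessions <- function(dir) {
  headers <- sort(list.files(dir, pattern = "_session\\.json$",
                             full.names = TRUE))
  if (length(headers) == 0L) {
    stop("no session headers (*_session.json) found in ", dir,
         call. = FALSE)
  }
  lapply(headers, read_session)
}

run_config_keys <- c("seed", "table", "table_file", "cohorts", "analysis")
cohort_keys <- c("n", "cohort", "base_latency", "scan_speed", "aim_time",
                 "noise_sigma", "lateral_bias", "bias_gain",
                 "starting_level", "config")
analysis_keys <- c("plateau_tolerance", "plots")

#' Load and validate a run configuration
#'
#' A run config is a JSON object with a master `seed`, an optional inline
#' difficulty `table` (or `table_file` path), a list of `cohorts` (each
#' either a preset name — `"young"`, `"elderly"`, `"neglect"`, optionally
#' with `n` — or a full [cohort_spec()] field set with per-cohort task
#' `config` overrides), and optional `analysis` options. Unknown keys are
#' rejected by name; defaults (30 targets/round, 10 rounds, the standard
#' difficulty table) fill anything omitted.
#'
#' @param path Path to the JSON file.
#' @return List of class `run_config`: `seed`, `table`, `cohorts`
#'   (list of [cohort_spec()]), `analysis`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), run_config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(obj$cohorts) || length(obj$cohorts) == 0L) {
    stop("config must define at least one cohort", call. = FALSE)
  }
  table <- if (!is.null(obj$table_file)) {
    read_difficulty_table(obj$table_file)
  } else if (!is.null(obj$table)) {
    pick <- function(x) list(lifetime = x$lifetime_s, speed = x$speed_deg_s,
                             up = x$up_pct, down = x$down_pct)
    difficulty_table(pick(obj$table$level1), pick(obj$table$change),
                     n_levels = obj$table$n_levels)
  } else default_table()
  cohort_list <- obj$cohorts
  if (is.data.frame(cohort_list)) {
    cohort_list <- lapply(seq_len(nrow(cohort_list)), function(i)
      as.list(cohort_list[i, , drop = FALSE]))
  }
  cohorts <- lapply(cohort_list, parse_cohort)
  for (spec in cohorts) {
    # surface invalid task overrides at load time, not mid-simulation
    do.call(task_config, c(spec$config_overrides,
                           list(starting_level = spec$starting_level)))
  }
  ana <- as.list(obj$analysis)
  unknown <- setdiff(names(ana), analysis_keys)
  if (length(unknown) > 0L) {
    stop("unknown analysis key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(ana$plateau_tolerance)) ana$plateau_tolerance <- 1
  if (is.null(ana$plots)) ana$plots <- FALSE
  structure(
    list(seed = if (is.null(obj$seed)) 1L else as.integer(obj$seed),
         table = table, cohorts = cohorts, analysis = ana),
    class = "run_config"
  )
}

parse_cohort <- function(co) {
  co <- as.list(co)
  co[vapply(co, function(x) all(is.na(unlist(x))), logical(1))] <- NULL
  unknown <- setdiff(names(co), cohort_keys)
  if (length(unknown) > 0L) {
    stop("unknown cohort key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  presets <- list(young = young_cohort, elderly = elderly_cohort,
                  neglect = neglect_cohort)
  full <- c("base_latency", "scan_speed", "aim_time", "noise_sigma")
  if (!is.null(co$cohort) && co$cohort %in% names(presets) &&
      !any(full %in% names(co))) {
    spec <- if (is.null(co$n)) presets[[co$cohort]]() else
      presets[[co$cohort]](n = co$n)
    if (!is.null(co$starting_level)) {
      spec$starting_level <- as.integer(co$starting_level)
    }
    if (!is.null(co$config)) {
      spec$config_overrides <- utils::modifyList(spec$config_overrides,
                                                 as.list(co$config))
    }
    if (!is.null(co$lateral_bias)) spec$lateral_bias <-
        as.numeric(unlist(co$lateral_bias))
    return(spec)
  }
  miss <- setdiff(c("n", "cohort", full), names(co))
  if (length(miss) > 0L) {
    stop("cohort spec missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort_spec(
    n = co$n, cohort = co$cohort,
    base_latency = as.numeric(unlist(co$base_latency)),
    scan_speed = as.numeric(unlist(co$scan_speed)),
    aim_time = as.numeric(unlist(co$aim_time)),
    noise_sigma = as.numeric(unlist(co$noise_sigma)),
    lateral_bias = if (is.null(co$lateral_bias)) 0 else
      as.numeric(unlist(co$lateral_bias)),
    bias_gain = if (is.null(co$bias_gain)) 2 else
      as.numeric(unlist(co$bias_gain)),
    starting_level = if (is.null(co$starting_level)) 1L else
      co$starting_level,
    config_overrides = as.list(co$config)
  )
}

#' Run a full simulation described by a run config
#'
#' Generates every cohort under the master seed (each cohort gets a
#' deterministic sub-seed) and, when `out_dir` is given, writes all
#' session logs plus a `run.json` manifest carrying the package version,
#' the master seed and a hash of the resolved configuration.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Optional output directory.
#' @param seed Optional override of the config's master seed.
#' @return List of `session_record`s (all cohorts, flattened).
#' @export
run_simulation <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  master <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(master)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(config$cohorts))
  sessions <- list()
  for (i in seq_along(config$cohorts)) {
    sessions <- c(sessions,
                  generate_cohort(config$cohorts[[i]], seed = sub_seeds[i],
                                  table = config$table))
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (s in sessions) write_session(s, out_dir)
    manifest <- list(
      package_version =
        as.character(utils::packageVersion("birdsearch")),
      master_seed = master,
      config_hash = config_hash(config),
      n_sessions = length(sessions),
      cohorts = vapply(config$cohorts, `[[`, character(1), "cohort")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sessions
}

# Structural hash of a resolved run config (stable across sessions).
config_hash <- function(config) {
  canon <- paste(deparse(config, control = "all"), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(canon) *
                        (seq_len(nchar(canon)) %% 997)) %% .Machine$integer.max)
}

#' Analyse a set of sessions and write the result tables
#'
#' Emits the level-difference trajectory per cohort
#' (`trajectory.csv`), per-session metrics (`session_metrics.csv`), and
#' group statistics (`group_stats.json`: per-cohort mean search times, a
#' Welch t test between the first two healthy cohorts when present, and
#' CoC-vs-search-time Pearson correlations per hemispace for cohorts
#' carrying CoC metadata).
#'
#' @param sessions List of `session_record`s (e.g. [read_sessions()]).
#' @param out_dir Optional output directory for the CSV/JSON artifacts.
#' @param plateau_tolerance Passed to [detect_plateau()].
#' @return List `(trajectory, metrics, group_stats)`, invisibly written
#'   to `out_dir` when given.
#' @export
analyze_sessions <- function(sessions, out_dir = NULL,
                             plateau_tolerance = 1) {
  cohorts <- vapply(sessions, `[[`, character(1), "cohort")
  traj <- do.call(rbind, lapply(unique(cohorts), function(co) {
    tr <- level_difference_trajectory(sessions[cohorts == co])
    cbind(cohort = co, tr)
  }))
  metrics <- session_metrics(sessions, plateau_tolerance)
  stats_out <- list()
  for (co in unique(cohorts)) {
    m <- metrics[metrics$cohort == co, ]
    stats_out[[co]] <- list(
      n = nrow(m),
      mean_search_time_s = mean(m$mean_search_time_s, na.rm = TRUE),
      sd_search_time_s = stats::sd(m$mean_search_time_s)
    )
  }
  healthy <- unique(cohorts)[!unique(cohorts) %in% "neglect"]
  if (length(healthy) >= 2L) {
    a <- metrics$mean_search_time_s[metrics$cohort == healthy[1]]
    b <- metrics$mean_search_time_s[metrics$cohort == healthy[2]]
    if (length(a) >= 2L && length(b) >= 2L) {
      stats_out$search_time_t_test <- c(
        list(groups = healthy[1:2]),
        welch_t(a[!is.na(a)], b[!is.na(b)]))
    }
  }
  with_coc <- metrics[!is.na(metrics$coc), ]
  if (nrow(with_coc) >= 3L) {
    ok_l <- !is.na(with_coc$left_search_time_s)
    ok_r <- !is.na(with_coc$right_search_time_s)
    stats_out$coc_correlations <- list(
      left = pearson(with_coc$coc[ok_l],
                     with_coc$left_search_time_s[ok_l]),
      right = pearson(with_coc$coc[ok_r],
                      with_coc$right_search_time_s[ok_r]),
      overall = pearson(with_coc$coc,
                        with_coc$mean_search_time_s)
    )
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "session_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trajectory = traj, metrics = metrics, group_stats = stats_out)
}
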