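#' Difficulty table for the adaptive visual search task
#'
#' The task's difficulty is organised in a fixed number of levels (15 by
#' default). Level 1 sets the easiest target behaviour (long lifetime, slow
#' movement, lenient promotion/demotion thresholds); each subsequent level
#' applies a fixed signed change to all four parameters. A round's outcome
#' (percent of targets found) is compared against the current level's
#' thresholds to decide the next round's level.
#'
#' @param level1 Named list with the level-1 values: `lifetime` (seconds),
#'   `speed` (degrees/second), `up` and `down` (percent-found thresholds).
#' @param change Named list of per-level signed deltas with the same names.
#' @param n_levels Number of difficulty levels (default 15).
#'
#' @return An object of class `difficulty_table`.
#' @seealso [default_table()], [level_params()], [next_level()]
#' @export
difficulty_table <- function(level1, change, n_levels = 15L) {
  needed <- c("lifetime", "speed", "up", "down")
  for (nm in list(level1, change)) {
    if (!is.list(nm) || !all(needed %in% names(nm))) {
      stop("level1 and change must be named lists with fields: ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1L) {
    stop("n_levels must be a positive integer", call. = FALSE)
  }
  tab <- structure(
    list(
      n_levels = n_levels,
      level1 = lapply(level1[needed], as.numeric),
      change = lapply(change[needed], as.numeric)
    ),
    class = "difficulty_table"
  )
  validate_difficulty_table(tab)
  tab
}

validate_difficulty_table <- function(tab) {
  for (lev in seq_len(tab$n_levels)) {
    p <- level_params(tab, lev, .validate = FALSE)
    if (p$lifetime <= 0 || p$speed <= 0) {
      stop("invalid table: lifetime/speed not strictly positive at level ",
           lev, call. = FALSE)
    }
    if (!(p$level_down_threshold < p$level_up_threshold)) {
      stop("invalid table: level_down_threshold must be below ",
           "level_up_threshold at level ", lev, call. = FALSE)
    }
    if (p$level_up_threshold <= 0 || p$level_up_threshold >= 100 ||
        p$level_down_threshold <= 0 || p$level_down_threshold >= 100) {
      stop("invalid table: thresholds must lie in (0, 100) at level ",
           lev, call. = FALSE)
    }
  }
  invisible(tab)
}

#' Default 15-level difficulty table
#'
#' Level 1: target lifetime 15 s, speed 2 deg/s, level-up threshold 70%,
#' level-down threshold 60%. Per-level change: lifetime -0.786 s,
#' speed +2.36 deg/s, both thresholds +1.42 percentage points. Fifteen
#' levels take the task from slow, long-lived targets to fast, short-lived
#' ones (level 15: roughly 4 s lifetime at 35 deg/s).
#'
#' @return A [difficulty_table()].
#' @examples
#' tab <- default_table()
#' level_params(tab, 6)$speed # 13.8
#' @export
default_table <- function() {
  difficulty_table(
    level1 = list(lifetime = 15, speed = 2, up = 70, down = 60),
    change = list(lifetime = -0.786, speed = 2.36, up = 1.42, down = 1.42),
    n_levels = 15L
  )
}

#' Resolve the parameters of one difficulty level
#'
#' Each parameter at level `l` is the level-1 value plus `(l - 1)` times the
#' per-level change. Parameters are generated from level 1 by the printed
#' deltas, not by interpolating towards the level-15 endpoints; the two
#' differ only by display rounding at the top level.
#'
#' @param table A [difficulty_table()].
#' @param level Integer level index in `[1, n_levels]`.
#' @param .validate Internal; skip range checking during table validation.
#'
#' @return A list of class `level_parameters` with fields `level`,
#'   `lifetime` (s), `speed` (deg/s), `level_up_threshold` and
#'   `level_down_threshold` (percent).
#' @export
level_params <- function(table, level, .validate = TRUE) {
  stopifnot(inherits(table, "difficulty_table"))
  if (.validate &&
      (length(level) != 1L || is.na(level) || level < 1 ||
       level > table$n_levels || level != as.integer(level))) {
    stop("level must be an integer in [1, ", table$n_levels, "]",
         call. = FALSE)
  }
  k <- as.numeric(level) - 1
  structure(
    list(
      level = as.integer(level),
      lifetime = table$level1$lifetime + k * table$change$lifetime,
      speed = table$level1$speed + k * table$change$speed,
      level_up_threshold = table$level1$up + k * table$change$up,
      level_down_threshold = table$level1$down + k * table$change$down
    ),
    class = "level_parameters"
  )
}

#' All levels of a difficulty table as a data frame
#'
#' @param table A [difficulty_table()].
#' @return A data.frame with one row per level and columns `level`,
#'   `lifetime_s`, `speed_deg_s`, `up_pct`, `down_pct`.
#' @export
resolve_table <- function(table) {
  stopifnot(inherits(table, "difficulty_table"))
  rows <- lapply(seq_len(table$n_levels), function(l) {
    p <- level_params(table, l)
    data.frame(level = p$level, lifetime_s = p$lifetime,
               speed_deg_s = p$speed, up_pct = p$level_up_threshold,
               down_pct = p$level_down_threshold)
  })
  do.call(rbind, rows)
}

#' Percent of targets found in a round
#'
#' No rounding is applied; callers round for display only.
#'
#' @param n_found Number of targets found, in `[0, n_targets]`.
#' @param n_targets Number of targets presented; must be positive.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_found(25, 30) # 83.33...
#' @export
percent_found <- function(n_found, n_targets) {
  if (length(n_targets) != 1L || is.na(n_targets) || n_targets <= 0) {
    stop("n_targets must be a positive count", call. = FALSE)
  }
  if (any(is.na(n_found)) || any(n_found < 0) || any(n_found > n_targets)) {
    stop("n_found must lie in [0, n_targets]", call. = FALSE)
  }
  100 * n_found / n_targets
}

#' Level-switching rule between rounds
#'
#' Strict threshold comparison: a percent-found strictly above the current
#' level's level-up threshold promotes, strictly below the level-down
#' threshold demotes, and anything in between (including equality with
#' either threshold) holds the level. The result is clamped to
#' `[1, n_levels]`; there is no level 0 or 16.
#'
#' @param table A [difficulty_table()].
#' @param level Current level, in `[1, n_levels]`.
#' @param pct Percent of targets found in the round just played, in
#'   `[0, 100]`. Compared unrounded.
#' @return The next round's level (integer).
#' @examples
#' tab <- default_table()
#' next_level(tab, 6, percent_found(25, 30)) # 7
#' next_level(tab, 6, percent_found(15, 30)) # 5
#' @export
next_level <- function(table, level, pct) {
  stopifnot(inherits(table, "difficulty_table"))
  if (length(level) != 1L || is.na(level) || level < 1 ||
      level > table$n_levels) {
    stop("level must be in [1, ", table$n_levels, "]", call. = FALSE)
  }
  if (length(pct) != 1L || is.na(pct) || pct < 0 || pct > 100) {
    stop("pct must be in [0, 100]", call. = FALSE)
  }
  p <- level_params(table, level)
  out <- level
  if (pct > p$level_up_threshold) {
    out <- level + 1L
  } else if (pct < p$level_down_threshold) {
    out <- level - 1L
  }
  as.integer(min(max(out, 1L), table$n_levels))
}

#' @export
print.difficulty_table <- function(x, ...) {
  cat(sprintf("<difficulty_table> %d levels\n", x$n_levels))
  cat(sprintf("  level 1: lifetime %.3g s, speed %.3g deg/s, up >%.3g%%, down <%.3g%%\n",
              x$level1$lifetime, x$level1$speed, x$level1$up, x$level1$down))
  cat(sprintf("  change/level: %+.3g s, %+.3g deg/s, %+.3g, %+.3g\n",
              x$change$lifetime, x$change$speed, x$change$up, x$change$down))
  invisible(x)
}

#' @export
print.level_parameters <- function(x, ...) {
  cat(sprintf(
    "<level %d> lifetime %.4g s, speed %.4g deg/s, up >%.4g%%, down <%.4g%%\n",
    x$level, x$lifetime, x$speed, x$level_up_threshold,
    x$level_down_threshold))
  invisible(x)
}

#' Write a difficulty table to JSON
#'
#' Schema: `{n_levels, level1: {lifetime_s, speed_deg_s, up_pct, down_pct},
#' change: {lifetime_s, speed_deg_s, up_pct, down_pct}}`.
#'
#' @param table A [difficulty_table()].
#' @param path Output file path.
#' @export
write_difficulty_table <- function(table, path) {
  stopifnot(inherits(table, "difficulty_table"))
  obj <- list(
    n_levels = table$n_levels,
    level1 = list(lifetime_s = table$level1$lifetime,
                  speed_deg_s = table$level1$speed,
                  up_pct = table$level1$up,
                  down_pct = table$level1$down),
    change = list(lifetime_s = table$change$lifetime,
                  speed_deg_s = table$change$speed,
                  up_pct = table$change$up,
                  down_pct = table$change$down)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a difficulty table from JSON
#'
#' @param path File written by [write_difficulty_table()].
#' @return A [difficulty_table()].
#' @export
read_difficulty_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("n_levels", "level1", "change")) {
    if (is.null(obj[[fld]])) {
      stop("difficulty table JSON missing field '", fld, "'", call. = FALSE)
    }
  }
  pick <- function(x) list(lifetime = x[["lifetime_s"]],
                           speed = x[["speed_deg_s"]],
                           up = x[["up_pct"]], down = x[["down_pct"]])
  difficulty_table(pick(as.list(obj$level1)), pick(as.list(obj$change)),
                   n_levels = obj$n_levels)
}
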