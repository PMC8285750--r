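#' Level-difference trajectory across sessions
#'
#' For each session the per-round level difference is the level in round r
#' minus the starting level (round 1 is 0 by construction). Sessions may
#' have unequal round counts (patients often play fewer rounds); each round
#' pools only the sessions that reached it, and the standard error is
#' sd/sqrt(n) over those contributors (0 when a single session
#' contributes).
#'
#' @param sessions List of [run_session()] records, or a list of integer
#'   level trajectories.
#' @return Data.frame with columns `round`, `mean_diff`, `se`, `n`.
#' @export
level_difference_trajectory <- function(sessions) {
  trajs <- trajectories_of(sessions)
  if (length(trajs) == 0L) {
    stop("need at least one session", call. = FALSE)
  }
  diffs <- lapply(trajs, function(tr) tr - tr[1])
  max_r <- max(lengths(diffs))
  rows <- lapply(seq_len(max_r), function(r) {
    vals <- unlist(lapply(diffs, function(d) if (length(d) >= r) d[r]))
    n <- length(vals)
    se <- if (n > 1L) stats::sd(vals) / sqrt(n) else 0
    data.frame(round = r, mean_diff = mean(vals), se = se, n = n)
  })
  do.call(rbind, rows)
}

trajectories_of <- function(sessions) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  lapply(sessions, function(s) {
    tr <- if (inherits(s, "session_record")) s$level_trajectory else s
    if (!is.numeric(tr) || length(tr) < 1L) {
      stop("each session must carry a non-empty level trajectory",
           call. = FALSE)
    }
    tr
  })
}

#' Detect the balance-point plateau of a level trajectory
#'
#' The plateau marks the balance point of the adaptive difficulty scaling:
#' the stretch over which the level no longer changes (materially) between
#' rounds, i.e. the player's performance sits between the level-down and
#' level-up thresholds. Returns the earliest round r whose level holds
#' unchanged into round r+1 and such that the levels from r to the end
#' span at most `tolerance` levels, provided that window covers at least
#' 3 rounds; `NULL` when no such round exists. (The hold-into-next-round
#' condition marks the entry into the plateau: a round from which the
#' level "did not change anymore", rather than the last round of the
#' climb that merely happens to sit within the terminal band.)
#'
#' @param trajectory Integer vector of per-round levels (>= 3 rounds).
#' @param tolerance Maximum max-minus-min level span inside the plateau
#'   window (default 1).
#' @return List `(plateau_start_round, plateau_level)` with the plateau
#'   level the rounded mean of the window, or `NULL`.
#' @examples
#' detect_plateau(c(8, 9, 10, 10, 10, 10)) # starts at round 3, level 10
#' @export
detect_plateau <- function(trajectory, tolerance = 1) {
  if (!is.numeric(trajectory) || length(trajectory) < 3L) {
    stop("trajectory must have at least 3 rounds", call. = FALSE)
  }
  n <- length(trajectory)
  for (r in seq_len(n - 2L)) {
    win <- trajectory[r:n]
    if (trajectory[r + 1L] == trajectory[r] &&
        max(win) - min(win) <= tolerance) {
      return(list(plateau_start_round = r,
                  plateau_level = as.integer(round(mean(win)))))
    }
  }
  NULL
}

#' Summarise a controller hand trace
#'
#' Lateral summary statistics of the recorded controller x position. The
#' shift index is the mean x normalized by the 1 m workspace half-width,
#' so it lies in `[-1, 1]`; positive values indicate the rightward shift
#' of movement typical of left hemispatial neglect.
#'
#' @param trace Data.frame with columns `t_s`, `x_m`, `y_m` (from
#'   [generate_hand_trace()]), or a [run_session()] record carrying one.
#' @return List of class `hand_trace_summary`: `mean_x`, `median_x`,
#'   `iqr_x`, `shift_index`.
#' @export
hand_trace_summary <- function(trace) {
  if (inherits(trace, "session_record")) trace <- trace$hand_trace
  if (!is.data.frame(trace) || nrow(trace) == 0L ||
      !all(c("x_m", "y_m") %in% names(trace))) {
    stop("trace must be a non-empty data.frame with x_m and y_m",
         call. = FALSE)
  }
  half <- 1
  structure(
    list(mean_x = mean(trace$x_m),
         median_x = stats::median(trace$x_m),
         iqr_x = stats::IQR(trace$x_m),
         shift_index = mean(trace$x_m) / half),
    class = "hand_trace_summary"
  )
}

#' @export
print.hand_trace_summary <- function(x, ...) {
  cat(sprintf(
    "<hand_trace_summary> mean x %.3f m, median %.3f m, IQR %.3f m, shift index %.3f\n",
    x$mean_x, x$median_x, x$iqr_x, x$shift_index))
  invisible(x)
}

questionnaire_ranges <- list(SUS = c(1, 5), SSQ = c(1, 4),
                             IPQ = c(1, 5), PGTQ = c(1, 7))

#' Score a questionnaire response
#'
#' System Usability Scale (SUS; 5-point items) and Simulator Sickness
#' Questionnaire (SSQ; 4-point items) are scored as the mean over their
#' items. Igroup Presence Questionnaire (IPQ; 5-point) and Perception of
#' Game Training Questionnaire (PGTQ; 7-point) items each probe a distinct
#' aspect and are returned per item, unaggregated.
#'
#' @param instrument One of `"SUS"`, `"SSQ"`, `"IPQ"`, `"PGTQ"`.
#' @param items Numeric item scores within the instrument's Likert range.
#' @return A single mean score (SUS, SSQ) or the item vector (IPQ, PGTQ).
#' @examples
#' score_questionnaire("SUS", c(5, 4, 5)) # 4.67
#' @export
score_questionnaire <- function(instrument, items) {
  instrument <- match.arg(instrument, names(questionnaire_ranges))
  rng <- questionnaire_ranges[[instrument]]
  if (!is.numeric(items) || length(items) == 0L || any(is.na(items)) ||
      any(items < rng[1]) || any(items > rng[2])) {
    stop(instrument, " items must lie in [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  if (instrument %in% c("SUS", "SSQ")) mean(items) else items
}

#' Welch's two-sided t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value, as used to compare group mean search
#' times.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return List `(t, df, p)`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("both groups have zero variance; t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson r and its two-sided p value via the t transformation,
#' as used to relate neglect severity (CoC) to search times.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List `(r, p)`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Per-session metrics table for a set of sessions
#'
#' One row per session: overall and per-hemispace mean search times, the
#' hand-trace lateral shift index, plateau (if any), and the lateral bias
#' / CoC metadata when present.
#'
#' @param sessions List of [run_session()] records.
#' @param plateau_tolerance Passed to [detect_plateau()].
#' @return A data.frame.
#' @export
session_metrics <- function(sessions, plateau_tolerance = 1) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    hemi <- hemispace_search_times(s)
    mst <- tryCatch(mean_search_time(s), error = function(e) NA_real_)
    shift <- if (!is.null(s$hand_trace) && nrow(s$hand_trace) > 0L) {
      hand_trace_summary(s$hand_trace)$shift_index
    } else NA_real_
    pl <- if (length(s$level_trajectory) >= 3L) {
      detect_plateau(s$level_trajectory, plateau_tolerance)
    } else NULL
    data.frame(
      participant_id = s$participant_id,
      cohort = s$cohort,
      n_rounds = length(s$rounds),
      n_targets = nrow(s$events),
      n_found = sum(s$events$found),
      mean_search_time_s = mst,
      left_search_time_s = unname(hemi["left"]),
      right_search_time_s = unname(hemi["right"]),
      shift_index = shift,
      plateau_start_round = if (is.null(pl)) NA_integer_ else
        pl$plateau_start_round,
      plateau_level = if (is.null(pl)) NA_integer_ else pl$plateau_level,
      lateral_bias = if (is.null(s$metadata$lateral_bias)) NA_real_ else
        s$metadata$lateral_bias,
      coc = if (is.null(s$metadata$coc)) NA_real_ else s$metadata$coc
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
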