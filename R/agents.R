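#' Synthetic player agent
#'
#' A minimal behavioural response model standing in for a human player.
#' The time to find and tag a target at azimuth `a` (degrees from the
#' midsagittal plane) is
#'
#' \deqn{t = (L + |a|/v + A) \cdot (1 + g\lambda \cdot [a < 0]) \cdot \epsilon}
#'
#' where `L` is the cue-to-search base latency, `v` the angular scan speed,
#' `A` the tagging (aim) latency, `g` the bias gain, `lambda` the lateral
#' bias, and `epsilon` a lognormal noise factor with median 1 and log-sd
#' `noise_sigma`. The multiplicative left-hemispace penalty `1 + g*lambda`
#' emulates the slowed contralesional search characteristic of left
#' hemispatial neglect; `lambda = 0` gives a symmetric (healthy) player.
#' The target is found iff `t` does not exceed the level's target lifetime.
#'
#' @param base_latency Seconds from alerting cue to search onset (>= 0).
#' @param scan_speed Angular search rate in degrees/second (> 0).
#' @param aim_time Tagging latency after detection, seconds (>= 0).
#' @param noise_sigma Log-sd of the multiplicative lognormal noise (>= 0);
#'   0 gives the deterministic closed form.
#' @param lateral_bias Lateral bias lambda in `[0, 1]`; 0 = symmetric.
#' @param bias_gain Multiplier (>= 0) scaling the left-hemispace penalty.
#'
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(base_latency = 0.4, scan_speed = 30,
                          aim_time = 0.2, noise_sigma = 0,
                          lateral_bias = 0, bias_gain = 2) {
  if (base_latency < 0 || aim_time < 0 || noise_sigma < 0 || bias_gain < 0) {
    stop("latencies, noise_sigma and bias_gain must be non-negative",
         call. = FALSE)
  }
  if (scan_speed <= 0) stop("scan_speed must be positive", call. = FALSE)
  if (lateral_bias < 0 || lateral_bias > 1) {
    stop("lateral_bias must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(base_latency = base_latency, scan_speed = scan_speed,
         aim_time = aim_time, noise_sigma = noise_sigma,
         lateral_bias = lateral_bias, bias_gain = bias_gain),
    class = "agent_profile"
  )
}

#' @export
print.agent_profile <- function(x, ...) {
  cat(sprintf(
    "<agent_profile> latency %.3g s, scan %.3g deg/s, aim %.3g s, sigma %.3g, lambda %.3g (gain %.3g)\n",
    x$base_latency, x$scan_speed, x$aim_time, x$noise_sigma,
    x$lateral_bias, x$bias_gain))
  invisible(x)
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes a group of agents to simulate: the number of participants,
#' sampling distributions for the agent parameters (each field either a
#' single number, used as-is, or a `c(min, max)` pair sampled uniformly
#' per participant), the starting level, and task-config overrides.
#'
#' @param n Number of participants.
#' @param cohort Label: `"young"`, `"elderly"` or `"neglect"` (free-form
#'   labels are accepted).
#' @param base_latency,scan_speed,aim_time,noise_sigma,lateral_bias Scalar
#'   or `c(min, max)` uniform range for the corresponding
#'   [agent_profile()] field.
#' @param bias_gain Scalar left-penalty gain shared by the cohort.
#' @param starting_level First round's difficulty level.
#' @param config_overrides Named list of [task_config()] overrides applied
#'   to every participant (e.g. `targets_per_round`, `n_rounds`,
#'   `speed_floor_override` for the patient task version).
#'
#' @return An object of class `cohort_spec`.
#' @seealso [young_cohort()], [elderly_cohort()], [neglect_cohort()],
#'   [generate_cohort()]
#' @export
cohort_spec <- function(n, cohort, base_latency, scan_speed, aim_time,
                        noise_sigma, lateral_bias = 0, bias_gain = 2,
                        starting_level = 1L, config_overrides = list()) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n)) {
    stop("cohort spec: n must be a positive integer", call. = FALSE)
  }
  chk_range <- function(x, nm, lo = 0, hi = Inf, open_lo = FALSE) {
    if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || any(is.na(x))) {
      stop("cohort spec: ", nm, " must be a scalar or c(min, max)",
           call. = FALSE)
    }
    if (length(x) == 2L && x[1] > x[2]) {
      stop("cohort spec: ", nm, " range has min > max", call. = FALSE)
    }
    bad <- if (open_lo) any(x <= lo) else any(x < lo)
    if (bad || any(x > hi)) {
      stop("cohort spec: ", nm, " out of valid range", call. = FALSE)
    }
    x
  }
  structure(
    list(
      n = as.integer(n), cohort = as.character(cohort),
      base_latency = chk_range(base_latency, "base_latency"),
      scan_speed = chk_range(scan_speed, "scan_speed", open_lo = TRUE),
      aim_time = chk_range(aim_time, "aim_time"),
      noise_sigma = chk_range(noise_sigma, "noise_sigma"),
      lateral_bias = chk_range(lateral_bias, "lateral_bias", hi = 1),
      bias_gain = chk_range(bias_gain, "bias_gain"),
      starting_level = as.integer(starting_level),
      config_overrides = config_overrides
    ),
    class = "cohort_spec"
  )
}

#' Default cohort presets
#'
#' Presets emulating the three study groups. Young healthy players: fast
#' scanning, low latency, little noise, no lateral bias, starting at
#' level 8. Elderly healthy players: slower scanning, longer latencies,
#' more variable, starting at level 5. Neglect patients: slow scanning,
#' long latencies, a lateral bias sampled per patient, the patient task
#' configuration (fewer targets per round, minimum target speed lowered
#' to 0.1 deg/s) and a low starting level. Agent parameter values were
#' calibrated so that the median per-target search times fall near the
#' healthy groups' observed means (about 1.5 s young, 1.7 s elderly);
#' see the package vignette for the rationale.
#'
#' @param n Number of participants (defaults: 21 young, 23 elderly,
#'   11 neglect).
#' @param lateral_bias Range of the neglect cohort's bias parameter.
#' @name cohort_presets
NULL

#' @rdname cohort_presets
#' @export
young_cohort <- function(n = 21) {
  cohort_spec(n, "young",
              base_latency = c(0.35, 0.5), scan_speed = c(35, 45),
              aim_time = c(0.3, 0.4), noise_sigma = 0.3,
              lateral_bias = 0, starting_level = 8L)
}

#' @rdname cohort_presets
#' @export
elderly_cohort <- function(n = 23) {
  cohort_spec(n, "elderly",
              base_latency = c(0.35, 0.55), scan_speed = c(25, 35),
              aim_time = c(0.2, 0.3), noise_sigma = 0.6,
              lateral_bias = 0, starting_level = 5L)
}

#' @rdname cohort_presets
#' @export
neglect_cohort <- function(n = 11, lateral_bias = c(0.1, 0.9)) {
  cohort_spec(n, "neglect",
              base_latency = c(0.6, 1.0), scan_speed = c(6, 10),
              aim_time = c(0.4, 0.6), noise_sigma = 0.4,
              lateral_bias = lateral_bias, bias_gain = 2,
              starting_level = 2L,
              config_overrides = list(targets_per_round = 8L,
                                      n_rounds = 10L,
                                      speed_floor_override = 0.1))
}
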