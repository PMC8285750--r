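#' Severity-recovery experiment
#'
#' Simulates a cohort of neglect patients varying only in the lateral bias
#' parameter and asks whether the bias severity measured on a cancellation
#' sheet (Center of Cancellation) is recovered by the in-game left-hemispace
#' search time. This is a controlled parameter-recovery design: every
#' patient shares one ability profile so that the lateralized impairment is
#' the only source of between-patient variance, and the task is played as a
#' short low-difficulty assessment block (starting level 1, three rounds)
#' so that target-lifetime censoring — which at the adaptive balance point
#' removes exactly the slowest searches — barely binds. Each patient also
#' performs one simulated cancellation test, linking the same bias
#' parameter to a CoC.
#'
#' @param n Number of simulated patients (default 20).
#' @param seed Master seed.
#' @param lambda_range Range of the lateral bias, sampled uniformly
#'   (default `c(0.1, 0.9)`).
#' @param profile Ability profile shared by all patients: an
#'   [agent_profile()] without the bias fields (defaults: base latency
#'   0.8 s, scan speed 15 deg/s, aim time 0.5 s, lognormal noise 0.4).
#' @param targets_per_round,n_rounds Assessment block size (default
#'   3 rounds of 50 targets, a session length patients of the task's
#'   target population realistically complete).
#' @return List: `metrics` ([session_metrics()] table with `coc` and
#'   `lateral_bias` columns), `r_left`, `r_right` (Pearson tests of CoC
#'   against the per-hemispace mean search times) and `r_overall`.
#' @export
severity_recovery <- function(n = 20, seed = 1L,
                              lambda_range = c(0.1, 0.9),
                              profile = agent_profile(
                                base_latency = 0.8, scan_speed = 15,
                                aim_time = 0.5, noise_sigma = 0.4),
                              targets_per_round = 50L, n_rounds = 3L) {
  spec <- cohort_spec(
    n, "neglect",
    base_latency = profile$base_latency,
    scan_speed = profile$scan_speed,
    aim_time = profile$aim_time,
    noise_sigma = profile$noise_sigma,
    lateral_bias = lambda_range,
    bias_gain = profile$bias_gain,
    starting_level = 1L,
    config_overrides = list(targets_per_round = targets_per_round,
                            n_rounds = n_rounds,
                            speed_floor_override = 0.1))
  sessions <- generate_cohort(spec, seed = seed, hand_trace = FALSE)
  metrics <- session_metrics(sessions)
  list(
    metrics = metrics,
    r_left = pearson(metrics$coc, metrics$left_search_time_s),
    r_right = pearson(metrics$coc, metrics$right_search_time_s),
    r_overall = pearson(metrics$coc, metrics$mean_search_time_s)
  )
}
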