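# Independent oracles, coded directly from the printed level-1 values and
# per-level changes, deliberately not sharing code with the package.

oracle_level_table <- function() {
  lev <- 1:15
  data.frame(
    level = lev,
    lifetime = 15 - 0.786 * (lev - 1),
    speed = 2 + 2.36 * (lev - 1),
    up = 70 + 1.42 * (lev - 1),
    down = 60 + 1.42 * (lev - 1)
  )
}

# Brute-force level switch: strict comparisons, clamped to [1, 15].
oracle_next_level <- function(level, n_found, n_targets = 30) {
  tab <- oracle_level_table()
  pct <- 100 * n_found / n_targets
  out <- level
  if (pct > tab$up[level]) out <- level + 1
  if (pct < tab$down[level]) out <- level - 1
  min(max(out, 1), 15)
}

# Textbook Welch t statistic and Welch-Satterthwaite df.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Textbook Pearson r and its two-sided p via the t transformation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Deterministic closed-form search time of the agent response model.
oracle_search_time <- function(agent, azimuth) {
  base <- agent$base_latency + abs(azimuth) / agent$scan_speed +
    agent$aim_time
  if (azimuth < 0) base * (1 + agent$bias_gain * agent$lateral_bias)
  else base
}

# A fast symmetric agent that finds every target at any level of the
# default table (max deterministic search time 0.4 + 60/40 + 0.1 = 2 s,
# below the level-15 lifetime of 3.996 s).
fast_agent <- function() agent_profile(base_latency = 0.4, scan_speed = 40,
                                       aim_time = 0.1, noise_sigma = 0)

# An agent that can never find a target (latency beyond every lifetime).
hopeless_agent <- function() agent_profile(base_latency = 20,
                                           scan_speed = 10, aim_time = 0,
                                           noise_sigma = 0)

make_target <- function(azimuth, lifetime = 15, level = 1L) {
  data.frame(round_index = 1L, level = as.integer(level), spawn_time_s = 0,
             azimuth_deg = azimuth, elevation_deg = 0, direction = 1L,
             speed_deg_s = 2, lifetime_s = lifetime,
             hemispace = if (azimuth < 0) "left" else "right",
             found = NA, search_time_s = NA_real_)
}
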