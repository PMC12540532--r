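# Shared fixtures: tiny noise-free configurations and hand-built traces.

quiet_config <- function(...) {
  sim_config(noise_sd = 0, rating_noise_sd = 0, participant_jitter = 0,
             trial_jitter = 0, ...)
}

# A hand-built trace with a piecewise-linear total load ramp (slope_N_s from
# t = start_s), a 518 g-style weight force, and exact photogate.
ramp_trace <- function(slope_N_s = 6, weight_N = 5.08, duration = 4,
                       fs = 400, start_s = 0) {
  time <- seq(0, duration - 1 / fs, by = 1 / fs)
  total <- pmax(0, pmin((time - start_s) * slope_N_s, 6))
  photogate <- total >= weight_N
  structure(list(
    sampling_rate = fs,
    time = time,
    grip = 0.6 * total,
    load = total / 2,
    platform = ifelse(photogate, 0, pmax(weight_N - total, 0)),
    photogate = photogate,
    true_liftoff_time = if (any(photogate)) {
      time[which(photogate)[1]]
    } else {
      NA_real_
    }
  ), class = "force_trace")
}

# Long-format random 2x2 cell-mean table for n participants.
random_cell_means <- function(n, seed = 1, subject_sd = 1, noise_sd = 1) {
  withr::with_seed(seed, {
    cm <- expand.grid(participant_id = seq_len(n),
                      cube = c("light", "heavy"),
                      switch = c("no_switch", "switch"),
                      stringsAsFactors = FALSE)
    cm$mean <- rep(stats::rnorm(n, 0, subject_sd), 4) +
      stats::rnorm(nrow(cm), 0, noise_sd)
    cm
  })
}

# Independent full sum-of-squares oracle for the two-way within-subject
# ANOVA (subject x A x B, one observation per cell).
anova_ss_oracle <- function(cm) {
  y <- stats::xtabs(mean ~ participant_id + cube + switch, cm)
  grand <- mean(y)
  n <- dim(y)[1]
  sm <- apply(y, 1, mean)
  am <- apply(y, 2, mean)
  bm <- apply(y, 3, mean)
  abm <- apply(y, c(2, 3), mean)
  sam <- apply(y, c(1, 2), mean)
  sbm <- apply(y, c(1, 3), mean)
  ssA <- 2 * n * sum((am - grand)^2)
  ssB <- 2 * n * sum((bm - grand)^2)
  ssAB <- n * sum((abm - outer(am, bm, "+") + grand)^2)
  ssSA <- 2 * sum((sam - outer(sm, am, "+") + grand)^2)
  ssSB <- 2 * sum((sbm - outer(sm, bm, "+") + grand)^2)
  ssS <- 4 * sum((sm - grand)^2)
  ssT <- sum((y - grand)^2)
  ssSAB <- ssT - ssS - ssA - ssB - ssAB - ssSA - ssSB
  list(
    F = c(cube = (ssA / 1) / (ssSA / (n - 1)),
          switch = (ssB / 1) / (ssSB / (n - 1)),
          interaction = (ssAB / 1) / (ssSAB / (n - 1))),
    partial_eta_sq = c(cube = ssA / (ssA + ssSA),
                       switch = ssB / (ssB + ssSB),
                       interaction = ssAB / (ssAB + ssSAB)),
    df_den = n - 1
  )
}
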