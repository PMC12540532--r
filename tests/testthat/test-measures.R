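test_that("platform reduction recovers the applied load until lift-off", {
  cfg <- quiet_config()
  ec <- extraction_config()
  tr <- simulate_trial(stimulus_spec(518), 518, cfg)
  red <- platform_reduction(tr, ec)
  W <- 518 / 1000 * 9.81
  # at rest the reduction is zero; after lift-off it plateaus at the weight
  expect_lt(max(abs(red[1:50])), 1e-6)
  expect_equal(red[length(red)], W, tolerance = 1e-6)
})

test_that("platform reduction equals a naive baseline-minus-channel loop", {
  cfg <- sim_config(seed = 8)
  ec <- extraction_config()
  tr <- withr::with_seed(8, simulate_trial(stimulus_spec(125), 125, cfg))
  red <- platform_reduction(tr, ec)
  filt <- lowpass_zero_phase(tr$platform, tr$sampling_rate, ec$filter)
  nb <- round(ec$baseline_window * tr$sampling_rate)
  baseline <- stats::median(filt[1:nb])
  naive <- numeric(length(filt))
  for (i in seq_along(filt)) naive[i] <- max(baseline - filt[i], 0)
  expect_equal(red, naive, tolerance = 1e-12)
})

test_that("a too-short baseline errors", {
  tr <- ramp_trace(duration = 0.1)
  expect_error(platform_reduction(tr, extraction_config()), "baseline")
})

test_that("extracted measures obey the physical bounds on a heavy lift", {
  m <- extract_measures(simulate_trial(stimulus_spec(518), 518,
                                       quiet_config()),
                        extraction_config())
  expect_gte(m$PLF, 518 / 1000 * 9.81)
  expect_gt(m$LPD1, 0)
  expect_gte(m$LPD1, m$LPD2)  # handle threshold is crossed first
  expect_lte(m$LF1st, m$PLF)
})

test_that("overshot light lifts keep LF1st but lose PF1st to truncation", {
  m <- extract_measures(simulate_trial(stimulus_spec(125), 518,
                                       quiet_config()),
                        extraction_config())
  expect_false(is.na(m$LF1st))
  expect_true(is.na(m$PF1st))
  reasons <- attr(m, "absences")
  expect_match(reasons$reason[reasons$measure == "PF1st"], "truncated")
})

test_that("LPD1 matches the closed-form crossing times on a linear ramp", {
  # 6 N/s ramp from 1 s: 0.2 N crossed at 0.2/6 s after start, the 5.08 N
  # weight at 5.08/6 s
  tr <- ramp_trace(slope_N_s = 6, weight_N = 5.08, start_s = 1)
  m <- extract_measures(tr, extraction_config())
  expect_equal(m$LPD1, (5.08 - 0.2) / 6, tolerance = 0.01)
  # platform sees full force: 0.4 N reduction crossed at 0.4/6 s
  expect_equal(m$LPD2, (5.08 - 0.4) / 6, tolerance = 0.01)
})

test_that("a trace without lift-off loses duration and platform measures", {
  cfg <- quiet_config(trial_duration = 1, correction_rate = 0.5)
  tr <- simulate_trial(stimulus_spec(518), 125, cfg)
  m <- extract_measures(tr, extraction_config())
  expect_false(is.na(m$PLF))
  expect_false(is.na(m$PGFR))
  expect_true(all(is.na(c(m$LPD1, m$LPD2, m$PPFR, m$PF1st))))
  expect_true("no lift-off" %in% attr(m, "absences")$reason)
})

test_that("heavy noise-free lifts give matching handle and platform rates", {
  cfg <- quiet_config()
  m <- extract_measures(simulate_trial(stimulus_spec(518), 518, cfg),
                        extraction_config())
  expect_equal(m$PPFR, m$PLFR, tolerance = 0.05)
})

test_that("raising overshoot never increases light-object PF1st capture", {
  cfg <- quiet_config()
  frac_present <- vapply(c(1.1, 1.6, 2.5, 4), function(alpha) {
    masses <- c(125, 518)
    present <- vapply(masses, function(exp_mass) {
      tr <- simulate_trial(stimulus_spec(125), exp_mass, cfg,
                           overrides = list(overshoot = alpha))
      !is.na(extract_measures(tr, extraction_config())$PF1st)
    }, logical(1))
    mean(present)
  }, numeric(1))
  expect_true(all(diff(frac_present) <= 0))
})

test_that("%-scores are centred, symmetric and convention-aware", {
  expect_equal(percent_scores(c(100, 300)), c(-50, 50))
  expect_equal(percent_scores(rep(7, 5)), rep(0, 5))
  withr::with_seed(2, est <- stats::rlnorm(50, 5, 1))
  s <- percent_scores(est)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(percent_scores(est, "mean_minus_score"), -s)
  # one ideal rating of each mass: difference of scores is ~122.2
  s2 <- percent_scores(c(125, 518))
  expect_equal(diff(s2), (518 - 125) / mean(c(125, 518)) * 100,
               tolerance = 1e-12)
  expect_error(percent_scores(numeric(0)), "at least one")
  expect_error(percent_scores(c(1, -2)), "positive")
})

test_that("the +/-3 SD trim keeps hand-checked and degenerate cases", {
  expect_true(all(trim_outliers(rep(4, 6))))        # SD = 0: retain all
  # mean 10, SD ~31.6: |100 - 10| = 90 < 3 * 31.6, so 100 is retained
  v <- c(rep(0, 9), 100)
  expect_equal(stats::sd(v), sqrt(sum((v - 10)^2) / 9))
  expect_true(all(trim_outliers(v)))
  # a genuinely extreme point is cut
  v2 <- withr::with_seed(1, c(stats::rnorm(20), 1e6))
  expect_false(trim_outliers(v2)[21])
  expect_error(trim_outliers(c(1, NA)), "at least 2")
})

test_that("trim exclusion rate on normal data sits near the 3-sigma tail", {
  withr::with_seed(99, x <- stats::rnorm(10000))
  frac <- mean(!trim_outliers(x))
  expect_gte(frac, 0.001)
  expect_lte(frac, 0.006)
})

test_that("condition means equal a naive group-by loop and handle NA", {
  withr::with_seed(6, {
    df <- expand.grid(participant_id = 1:3,
                      cube = c("light", "heavy"),
                      switch = c("no_switch", "switch"),
                      rep = 1:4, stringsAsFactors = FALSE)
    df$measure <- "PLFR"
    df$value <- stats::rnorm(nrow(df))
    df$value[1] <- NA
  })
  cm <- condition_means(df)
  for (i in seq_len(nrow(cm))) {
    sub <- df$value[df$participant_id == cm$participant_id[i] &
                      df$cube == cm$cube[i] & df$switch == cm$switch[i]]
    expect_equal(cm$mean[i], mean(sub, na.rm = TRUE))
  }
  # duplication leaves means unchanged
  cm2 <- condition_means(rbind(df, df))
  expect_equal(cm2$mean, cm$mean)
  # an empty cell errors with context
  df_bad <- df
  df_bad$value[df_bad$participant_id == 2 & df_bad$cube == "light" &
                 df_bad$switch == "switch"] <- NA
  expect_error(condition_means(df_bad), "participant 2")
  expect_error(condition_means(transform(df, switch = "discard")),
               "discard")
})
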