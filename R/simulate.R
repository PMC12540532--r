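# Synthetic dual-transducer lifting trials.
#
# The generator realizes the physical situation the analysis assumes: a
# participant programs a smooth (minimum-jerk) load-force ramp scaled to the
# weight they *expect*, the handle transducer records half the applied force,
# and the platform transducer records the reduction in downward force -- but
# only until the object leaves the surface, after which its reading is
# clamped at zero.  When the expected weight exceeds the actual weight the
# programmed ramp crosses the true weight force early, lift-off happens while
# the force rate is still rising, and the platform's view of the rate peak is
# truncated.  That truncation is the mechanism under study.

#' Stimulus specification
#'
#' @param mass Mass in grams.
#' @param side_length Cube side in centimetres (default 6, a 216 cm^3 cube).
#' @return A `stimulus_spec` list with derived `density` in g/cm^3.
#' @examples
#' stimulus_spec(125)$density  # 0.58 g/cm^3
#' @export
stimulus_spec <- function(mass, side_length = 6) {
  stopifnot(is.numeric(mass), mass > 0, side_length > 0)
  structure(list(mass = mass, side_length = side_length,
                 density = mass / side_length^3),
            class = "stimulus_spec")
}

#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: 29 participants, 81
#' lifts each (20 per transition condition), a 125 g and a 518 g cube of
#' 6 cm side, 400 Hz sampling and 4 s trials.
#'
#' @param n_participants Number of simulated participants.
#' @param n_per_transition Trials per ordered weight transition.
#' @param sampling_rate Hz.
#' @param trial_duration Trial length in seconds.
#' @param mass_light,mass_heavy Object masses in grams.
#' @param side_length Cube side in centimetres.
#' @param memory_weight Weight \eqn{\lambda} of the previous trial's mass in
#'   the running expectation (1 = pure one-back).
#' @param overshoot Target-force factor \eqn{\alpha \ge 1}: programmed load
#'   force plateaus at `overshoot` times the expected weight force.
#' @param rise_time Programmed ramp duration in seconds.
#' @param correction_rate Slope (N/s) of the secondary feedback ramp engaged
#'   when the programmed plateau falls short of the object's weight.
#' @param grip_ratio Grip force per unit total load force.
#' @param noise_sd Additive white sensor noise per channel, newtons.
#' @param perceptual_gain Contrast weight \eqn{\beta} of the expectation
#'   violation in heaviness ratings.
#' @param rating_noise_sd Log-scale SD of multiplicative rating noise.
#' @param reach_delay Seconds of quiet baseline before force onset (the
#'   reach-to-grasp period after the occlusion spectacles open).
#' @param participant_jitter Log-scale SD of per-participant perturbations of
#'   `grip_ratio`, `rise_time`, `overshoot` and `correction_rate`.
#' @param trial_jitter Log-scale SD of per-trial perturbations of
#'   `rise_time`, `overshoot` and `correction_rate`.
#' @param scale_sdlog Log-scale SD of the idiosyncratic per-participant
#'   magnitude-estimation scale.
#' @param seed Global integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 29,
                       n_per_transition = 20,
                       sampling_rate = 400,
                       trial_duration = 4,
                       mass_light = 125,
                       mass_heavy = 518,
                       side_length = 6,
                       memory_weight = 1,
                       overshoot = 1.1,
                       rise_time = 0.35,
                       correction_rate = 15,
                       grip_ratio = 0.6,
                       noise_sd = 0.005,
                       perceptual_gain = 0.05,
                       rating_noise_sd = 0.1,
                       reach_delay = 0.5,
                       participant_jitter = 0.10,
                       trial_jitter = 0.04,
                       scale_sdlog = 0.8,
                       seed = 1L) {
  cfg <- list(n_participants = n_participants,
              n_per_transition = n_per_transition,
              sampling_rate = sampling_rate,
              trial_duration = trial_duration,
              masses = list(light = stimulus_spec(mass_light, side_length),
                            heavy = stimulus_spec(mass_heavy, side_length)),
              memory_weight = memory_weight,
              overshoot = overshoot,
              rise_time = rise_time,
              correction_rate = correction_rate,
              grip_ratio = grip_ratio,
              noise_sd = noise_sd,
              perceptual_gain = perceptual_gain,
              rating_noise_sd = rating_noise_sd,
              reach_delay = reach_delay,
              participant_jitter = participant_jitter,
              trial_jitter = trial_jitter,
              scale_sdlog = scale_sdlog,
              seed = seed)
  stopifnot(is_count(cfg$n_participants), is_count(cfg$n_per_transition),
            cfg$sampling_rate > 0,
            cfg$trial_duration * cfg$sampling_rate >= 3,
            cfg$memory_weight >= 0, cfg$memory_weight <= 1,
            cfg$overshoot >= 1, cfg$grip_ratio >= 0, cfg$noise_sd >= 0,
            cfg$perceptual_gain >= 0, cfg$rise_time > 0,
              cfg$correction_rate > 0, cfg$reach_delay >= 0)
  structure(cfg, class = "sim_config")
}

# Minimum-jerk position profile on s in [0, 1].
minjerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

#' Simulate one lifting trial
#'
#' Generates the four recorded channels for a single lift of `stimulus` by a
#' lifter expecting `expected_mass`.  The total load force follows a
#' minimum-jerk ramp from 0 to `overshoot` x expected weight force over
#' `rise_time`; if that plateau is below the object's weight force a
#' secondary linear ramp at `correction_rate` continues until the weight is
#' exceeded (feedback correction).  Lift-off is the first sample at which
#' total load force reaches the weight force; the photogate flips there, and
#' from then on the platform reads zero (it cannot record past lift-off)
#' while the applied load holds its programmed course, capped at the larger
#' of plateau and weight force.  The handle records half the total load
#' force; grip force is `grip_ratio` times the load.  Independent Gaussian
#' noise (`noise_sd`) is added per channel.
#'
#' Trial-level parameter overrides (used by [simulate_cohort()] for
#' participant/trial jitter) can be passed via `overrides`.
#'
#' @param stimulus A [stimulus_spec()].
#' @param expected_mass Expected mass in grams (> 0).
#' @param config A [sim_config()].
#' @param overrides Named list overriding `overshoot`, `rise_time`,
#'   `grip_ratio`, `correction_rate` for this trial.
#' @return A `force_trace` list: `sampling_rate`, `time`, `grip`, `load`
#'   (handle reading, half of total), `platform`, `photogate`,
#'   `true_liftoff_time` (`NA` if the object never lifts within the trial).
#' @export
simulate_trial <- function(stimulus, expected_mass, config = sim_config(),
                           overrides = list()) {
  stopifnot(inherits(stimulus, "stimulus_spec"), expected_mass > 0)
  alpha <- overrides$overshoot %||% config$overshoot
  rise <- overrides$rise_time %||% config$rise_time
  r <- overrides$grip_ratio %||% config$grip_ratio
  corr_rate <- overrides$correction_rate %||% config$correction_rate
  fs <- config$sampling_rate
  n <- as.integer(round(config$trial_duration * fs))
  time <- (seq_len(n) - 1L) / fs
  W <- grams_to_newtons(stimulus$mass)
  target <- alpha * grams_to_newtons(expected_mass)

  s <- (time - config$reach_delay) / rise
  load_total <- target * minjerk(s)
  ramp_end <- config$reach_delay + rise
  if (target < W) {
    past <- time > ramp_end
    load_total[past] <- target + corr_rate * (time[past] - ramp_end)
  }
  load_total <- pmin(load_total, max(target, W))

  liftoff_idx <- which(load_total >= W)[1]
  if (is.na(liftoff_idx)) {
    photogate <- rep(FALSE, n)
    platform_clean <- pmax(W - load_total, 0)
    liftoff_time <- NA_real_
  } else {
    photogate <- seq_len(n) >= liftoff_idx
    platform_clean <- ifelse(photogate, 0, pmax(W - load_total, 0))
    liftoff_time <- (liftoff_idx - 1L) / fs
  }

  noise <- function() stats::rnorm(n, 0, config$noise_sd)
  structure(list(
    sampling_rate = fs,
    time = time,
    grip = r * load_total + noise(),
    load = load_total / 2 + noise(),
    platform = platform_clean + noise(),
    photogate = photogate,
    true_liftoff_time = liftoff_time
  ), class = "force_trace")
}

#' Generate a magnitude-estimation heaviness rating
#'
#' Rating = `scale` x actual mass x (1 + beta x (actual - expected)/actual)
#' x exp(eps), eps ~ N(0, `rating_noise_sd`), floored at a small positive
#' constant.  The contrast term makes an object feel heavier than its mass
#' when it is heavier than expected, and lighter when lighter than expected
#' -- the sequential assimilation effect.
#'
#' @param actual_mass,expected_mass Grams (> 0).
#' @param participant_scale The participant's idiosyncratic scale unit (> 0).
#' @param config A [sim_config()] (uses `perceptual_gain`,
#'   `rating_noise_sd`).
#' @return A positive rating.
#' @export
generate_rating <- function(actual_mass, expected_mass, participant_scale,
                            config = sim_config()) {
  stopifnot(actual_mass > 0, expected_mass > 0, participant_scale > 0)
  beta <- config$perceptual_gain
  eps <- if (config$rating_noise_sd > 0) {
    stats::rnorm(1, 0, config$rating_noise_sd)
  } else 0
  val <- participant_scale * actual_mass *
    (1 + beta * (actual_mass - expected_mass) / actual_mass) * exp(eps)
  max(val, 1e-6)
}

#' Simulate a full cohort of lifting sessions
#'
#' For each participant: draw an idiosyncratic rating scale (log-normal
#' around 1) and per-participant perturbations of grip ratio, rise time and
#' overshoot; generate a transition-balanced sequence from a
#' participant-specific substream seed; then run through the trials updating
#' the weight expectation \eqn{E_t = \lambda m_{t-1} + (1-\lambda) E_{t-1}}
#' (initialised at the mean of the two masses), simulating a trace and a
#' rating for each.  Each participant consumes an independent RNG substream
#' derived from `config$seed`, so results are fully deterministic and adding
#' participants never perturbs earlier ones.
#'
#' @param config A [sim_config()].
#' @param keep_traces Keep the full force traces in the returned records
#'   (default `TRUE`; set `FALSE` to save memory when only measures are
#'   needed downstream -- extraction then has to be done per trial via the
#'   `on_trial` callback).
#' @param on_trial Optional callback `function(record)` invoked on each
#'   complete trial record (with trace) before the trace is possibly
#'   dropped; its return value, if not `NULL`, is stored in the record's
#'   `extracted` field.
#' @return A list of trial records: `participant_id`, `trial_index`, `cube`,
#'   `switch`, `stimulus`, `expected_mass`, `magnitude_estimate`, `trace`
#'   (or `NULL`), `extracted` (if `on_trial` given).
#' @export
simulate_cohort <- function(config = sim_config(), keep_traces = TRUE,
                            on_trial = NULL) {
  records <- vector("list", config$n_participants * (4L * config$n_per_transition + 1L))
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    pseed <- substream_seed(config$seed, p)
    labels <- generate_balanced_sequence(config$n_per_transition,
                                         seed = substream_seed(pseed, 1L))
    conditions <- label_transitions(labels)
    recs <- with_seed(pseed, {
      scale_p <- stats::rlnorm(1, 0, config$scale_sdlog)
      jit <- function(x) x * stats::rlnorm(1, 0, config$participant_jitter)
      grip_p <- jit(config$grip_ratio)
      rise_p <- jit(config$rise_time)
      alpha_p <- max(1, jit(config$overshoot))
      corr_p <- jit(config$correction_rate)
      masses <- c(light = config$masses$light$mass,
                  heavy = config$masses$heavy$mass)
      expectation <- mean(masses)
      out <- vector("list", length(labels))
      for (i in seq_along(labels)) {
        stim <- config$masses[[labels[i]]]
        tjit <- function(x) x * stats::rlnorm(1, 0, config$trial_jitter)
        trace <- simulate_trial(stim, expectation, config,
                                overrides = list(overshoot = max(1, tjit(alpha_p)),
                                                 rise_time = tjit(rise_p),
                                                 grip_ratio = grip_p,
                                                 correction_rate = tjit(corr_p)))
        rating <- generate_rating(stim$mass, expectation, scale_p, config)
        rec <- list(participant_id = p,
                    trial_index = i,
                    cube = conditions$cube[i],
                    switch = conditions$switch[i],
                    stimulus = stim,
                    expected_mass = expectation,
                    magnitude_estimate = rating,
                    trace = trace)
        if (!is.null(on_trial)) rec$extracted <- on_trial(rec)
        if (!keep_traces) rec$trace <- NULL
        out[[i]] <- rec
        expectation <- config$memory_weight * stim$mass +
          (1 - config$memory_weight) * expectation
      }
      out
    })
    for (rec in recs) {
      k <- k + 1L
      records[[k]] <- rec
    }
  }
  records
}
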