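# Per-trial dependent measures.
#
# Nine scalars per trial: handle-derived PLF, PLFR, PGF, PGFR, LF1st, LPD1
# and platform-derived PPFR, PF1st, LPD2, plus the normalised perceptual
# %-score.  The platform physically cannot record past lift-off, so its peak
# searches stop there; the handles record through the hold phase.

MEASURE_NAMES <- c("PLF", "PLFR", "PGF", "PGFR", "LF1st", "LPD1",
                   "PPFR", "PF1st", "LPD2")

#' Extraction configuration
#'
#' @param handle_onset_threshold Newtons of *total* load force defining
#'   handle onset (default 0.2).
#' @param platform_onset_threshold Newtons of platform force reduction
#'   defining platform onset (default 0.4; the platform sees the full force,
#'   not half, hence double the handle threshold).
#' @param handle_force_scale Factor converting the single-digit handle load
#'   reading to total load force (default 2: the thumb is not instrumented).
#' @param filter A [filter_spec()] applied to every force channel before any
#'   detection or differentiation.
#' @param min_prominence First-peak prominence floor, as a fraction of the
#'   window maximum (default 0.05).
#' @param baseline_window Seconds of initial (pre-onset) platform signal used
#'   to estimate the resting reading (default 0.2).
#' @param pct_convention `%`-score sign convention: `"score_minus_mean"`
#'   (default; heavier-than-average estimates score positive) or the literal
#'   `"mean_minus_score"`.
#' @param trim_scope Grouping at which the +/-3 SD trim is applied:
#'   `"participant_cube"` (default), `"participant_cell"`, `"participant"`,
#'   or `"global"`.
#' @param trim_k SD multiplier for trimming (default 3).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(handle_onset_threshold = 0.2,
                              platform_onset_threshold = 0.4,
                              handle_force_scale = 2,
                              filter = filter_spec(),
                              min_prominence = 0.05,
                              baseline_window = 0.2,
                              pct_convention = c("score_minus_mean",
                                                 "mean_minus_score"),
                              trim_scope = c("participant_cube",
                                             "participant_cell",
                                             "participant", "global"),
                              trim_k = 3) {
  stopifnot(handle_onset_threshold > 0, platform_onset_threshold > 0,
            handle_force_scale > 0, inherits(filter, "filter_spec"),
            min_prominence >= 0, baseline_window > 0, trim_k > 0)
  structure(list(handle_onset_threshold = handle_onset_threshold,
                 platform_onset_threshold = platform_onset_threshold,
                 handle_force_scale = handle_force_scale,
                 filter = filter,
                 min_prominence = min_prominence,
                 baseline_window = baseline_window,
                 pct_convention = match.arg(pct_convention),
                 trim_scope = match.arg(trim_scope),
                 trim_k = trim_k),
            class = "extraction_config")
}

#' Platform force reduction
#'
#' The platform transducer reads the object's resting weight plus a bias;
#' lifting *reduces* that reading.  The reduction series is the baseline
#' (median of the filtered platform channel over the initial
#' `baseline_window` seconds) minus the filtered instantaneous reading,
#' clipped below at zero.  Up to lift-off it mirrors the applied total load
#' force; past lift-off it is flat at the weight force (truncation).
#'
#' @param trace A `force_trace`.
#' @param config An [extraction_config()].
#' @return Numeric series of force reduction in newtons.
#' @export
platform_reduction <- function(trace, config = extraction_config()) {
  fs <- trace$sampling_rate
  nb <- as.integer(round(config$baseline_window * fs))
  if (nb < 1L || nb > length(trace$platform)) {
    stop("trace too short for a ", config$baseline_window,
         " s baseline window", call. = FALSE)
  }
  filtered <- lowpass_zero_phase(trace$platform, fs, config$filter)
  baseline <- stats::median(filtered[seq_len(nb)])
  pmax(baseline - filtered, 0)
}

#' Extract the nine dependent measures from one trial
#'
#' Pipeline: (1) low-pass filter the force channels; (2) rescale the handle
#' load reading to total load force; (3) differentiate with the three-point
#' central difference; (4) detect handle onset (load > 0.2 N), platform
#' onset (reduction > 0.4 N) and lift-off (photogate); (5) take global peaks
#' -- PLF, PLFR, PGF, PGFR over [handle onset, trace end], PPFR over
#' [platform onset, lift-off]; (6) locate the first prominent rate peaks --
#' LF1st is the total load force at the first load-rate peak (handles record
#' through the hold phase, so the search spans [handle onset, trace end]),
#' PF1st the reduction at the first reduction-rate peak within [platform
#' onset, lift-off]; (7) durations LPD1 = lift-off - handle onset, LPD2 =
#' lift-off - platform onset.
#'
#' The platform transducer's recording *ends* at lift-off: samples after it
#' carry no information about the lift.  All platform-side processing
#' (filtering included) therefore uses only the samples before lift-off, so
#' that a force rate still rising when recording stops is correctly reported
#' as having no first peak, rather than acquiring an artificial one from
#' smoothing across the clamp corner.
#'
#' Any undetectable event yields `NA` for the measures depending on it (with
#' the reason recorded), never an error: a missing lift-off leaves the
#' handle measures computable but all duration and platform measures absent,
#' mirroring the platform's recording limitation; a reduction rate still
#' rising at lift-off (the truncation case) leaves PF1st absent.
#'
#' @param trial A trial record with a `trace` field, or a bare
#'   `force_trace`.
#' @param config An [extraction_config()].
#' @return One-row tibble of the nine measures plus onset/lift-off times,
#'   with attribute `"absences"`: a data frame of (measure, reason) for every
#'   `NA`.
#' @export
extract_measures <- function(trial, config = extraction_config()) {
  trace <- if (inherits(trial, "force_trace")) trial else trial$trace
  stopifnot(inherits(trace, "force_trace"))
  fs <- trace$sampling_rate
  n <- length(trace$load)
  end_time <- (n - 1L) / fs

  load_total <- config$handle_force_scale *
    lowpass_zero_phase(trace$load, fs, config$filter)
  grip <- lowpass_zero_phase(trace$grip, fs, config$filter)

  load_rate <- differentiate(load_total, fs)
  grip_rate <- differentiate(grip, fs)

  onset1 <- detect_onset(load_total, fs, config$handle_onset_threshold)
  liftoff <- detect_liftoff(trace$photogate, fs)

  # platform recording: only the samples strictly before lift-off exist
  minlen <- max(3L * (config$filter$order + 1L) + 1L,
                as.integer(round(config$baseline_window * fs)) + 1L)
  plat_n <- if (is.na(liftoff)) n else as.integer(round(liftoff * fs))
  platform_ok <- plat_n >= minlen
  if (platform_ok) {
    plat_trace <- trace
    plat_trace$platform <- trace$platform[seq_len(plat_n)]
    reduction <- platform_reduction(plat_trace, config)
    reduction_rate <- differentiate(reduction, fs)
    onset2 <- detect_onset(reduction, fs, config$platform_onset_threshold)
  } else {
    reduction <- NULL
    onset2 <- NA_real_
  }

  m <- stats::setNames(as.list(rep(NA_real_, length(MEASURE_NAMES))),
                       MEASURE_NAMES)
  absences <- list()
  note <- function(measure, reason) {
    absences[[length(absences) + 1L]] <<- data.frame(measure = measure,
                                                     reason = reason)
  }

  if (is.na(onset1)) {
    for (nm in c("PLF", "PLFR", "PGF", "PGFR", "LF1st", "LPD1")) {
      note(nm, "no handle onset: load force never exceeded threshold")
    }
  } else {
    m$PLF <- find_global_peak(load_total, fs, onset1, end_time)$value
    m$PLFR <- find_global_peak(load_rate, fs, onset1, end_time)$value
    m$PGF <- find_global_peak(grip, fs, onset1, end_time)$value
    m$PGFR <- find_global_peak(grip_rate, fs, onset1, end_time)$value
    fp <- find_first_rate_peak(load_rate, fs, onset1, end_time,
                               config$min_prominence)
    if (is.null(fp)) {
      note("LF1st", "no prominent load-rate peak in the handle record")
    } else {
      m$LF1st <- load_total[as.integer(round(fp$time * fs)) + 1L]
    }
    if (is.na(liftoff)) {
      note("LPD1", "no lift-off")
    } else {
      m$LPD1 <- liftoff - onset1
    }
  }

  if (is.na(liftoff)) {
    for (nm in c("PPFR", "PF1st", "LPD2")) note(nm, "no lift-off")
  } else if (!platform_ok) {
    for (nm in c("PPFR", "PF1st", "LPD2")) {
      note(nm, "platform recording too short before lift-off")
    }
  } else if (is.na(onset2)) {
    for (nm in c("PPFR", "PF1st", "LPD2")) {
      note(nm, "no platform onset: force reduction never exceeded threshold")
    }
  } else if (onset2 > liftoff) {
    for (nm in c("PPFR", "PF1st", "LPD2")) {
      note(nm, "platform onset after lift-off")
    }
  } else {
    m$LPD2 <- liftoff - onset2
    m$PPFR <- find_global_peak(reduction_rate, fs, onset2, liftoff)$value
    # The zero-phase filter's edge transient occupies the last
    # 3 * (order + 1) samples of the truncated recording and bends a rising
    # rate downward there, which would mimic a peak; a first peak must lie
    # clear of that region to count as captured.
    fp_end <- liftoff - (3L * (config$filter$order + 1L)) / fs
    fp <- if (fp_end > onset2) {
      find_first_rate_peak(reduction_rate, fs, onset2, fp_end,
                           config$min_prominence)
    } else {
      NULL
    }
    if (is.null(fp)) {
      note("PF1st", "reduction rate still rising at lift-off (truncated)")
    } else {
      m$PF1st <- reduction[as.integer(round(fp$time * fs)) + 1L]
    }
  }

  out <- tibble::as_tibble(m)
  out$handle_onset <- onset1
  out$platform_onset <- onset2
  out$liftoff <- liftoff
  attr(out, "absences") <- if (length(absences)) {
    do.call(rbind, absences)
  } else {
    data.frame(measure = character(), reason = character())
  }
  out
}

#' Normalise magnitude estimates to %-scores
#'
#' Each participant rates heaviness on their own free scale; %-scores make
#' them comparable: `(estimate - mean) / mean * 100` under the default
#' convention, so a participant's scores always average exactly zero and a
#' heavier-than-average object scores positive.
#'
#' @param estimates Positive ratings from one participant.
#' @param convention `"score_minus_mean"` (default) or the literal
#'   `"mean_minus_score"`, which flips the sign.
#' @return Numeric %-scores.
#' @examples
#' percent_scores(c(100, 300))  # -50, +50
#' @export
percent_scores <- function(estimates,
                           convention = c("score_minus_mean",
                                          "mean_minus_score")) {
  convention <- match.arg(convention)
  if (length(estimates) < 1L) {
    stop("need at least one estimate", call. = FALSE)
  }
  if (any(!is.finite(estimates) | estimates <= 0)) {
    stop("estimates must all be positive and finite", call. = FALSE)
  }
  m <- mean(estimates)
  s <- (estimates - m) / m * 100
  if (convention == "mean_minus_score") -s else s
}

#' Mask outliers beyond k standard deviations
#'
#' Single-pass rule: a value is excluded when |value - mean| > k x SD, with
#' mean and SD (n-1 denominator) computed once on the full input.  A
#' degenerate spread (SD = 0) retains everything.  `NA` values are passed
#' through as `NA` in the mask (they are already absent from analysis).
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param k SD multiplier (default 3).
#' @return Logical inclusion mask, same length as `values`.
#' @export
trim_outliers <- function(values, k = 3) {
  finite <- is.finite(values)
  if (sum(finite) < 2L) {
    stop("need at least 2 finite values to trim", call. = FALSE)
  }
  m <- mean(values[finite])
  s <- stats::sd(values[finite])
  if (s == 0) return(ifelse(finite, TRUE, NA))
  ifelse(finite, abs(values - m) <= k * s, NA)
}

#' Per-participant condition-cell means
#'
#' Averages retained trial values into the 2 (cube) x 2 (switch) design
#' cells for each participant and measure.  Discard-labelled trials must be
#' removed upstream; `NA` values simply drop out of their cell mean.  An
#' entirely empty cell is an error naming the participant, cell and measure,
#' since the repeated-measures ANOVA needs a complete table.
#'
#' @param measures Long tibble with columns `participant_id`, `cube`,
#'   `switch`, `measure`, `value`.
#' @return Tibble `participant_id`, `cube`, `switch`, `measure`, `mean`.
#' @export
condition_means <- function(measures) {
  stopifnot(all(c("participant_id", "cube", "switch", "measure", "value")
                %in% names(measures)))
  if (any(measures$switch == "discard")) {
    stop("discard-labelled trials must be removed before averaging",
         call. = FALSE)
  }
  out <- measures |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant_id", "cube", "switch", "measure")))) |>
    dplyr::summarise(mean = mean(value, na.rm = TRUE),
                     n = sum(is.finite(value)), .groups = "drop")
  empty <- out[out$n == 0L, ]
  if (nrow(empty) > 0L) {
    stop("empty design cell: participant ", empty$participant_id[1L],
         ", cube ", empty$cube[1L], ", switch ", empty$switch[1L],
         ", measure ", empty$measure[1L], call. = FALSE)
  }
  out$mean[!is.finite(out$mean)] <- NA_real_
  dplyr::select(out, -"n")
}
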