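# File formats and the end-to-end pipeline.
#
# Trace files: delimited text, one row per sample, columns time_s, grip_N,
# load_N, platform_N, photogate (0/1).  Session manifest: participant_id,
# trial_index, label, mass_g, magnitude_estimate, trace_filename.  Reports:
# measures table, ANOVA/contrast table, ICC table, dropped-value log, and a
# plain-text summary.

TRACE_COLUMNS <- c("time_s", "grip_N", "load_N", "platform_N", "photogate")

#' Write / read a force trace as delimited text
#'
#' @param trace A `force_trace`.
#' @param path File path (CSV).
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   validated `force_trace` with the sampling rate inferred from the time
#'   column (uniformity checked to 1 part in 1e4).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              grip_N = trace$grip,
                              load_N = trace$load,
                              platform_N = trace$platform,
                              photogate = as.integer(trace$photogate)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trace file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop("non-monotone time column in ", path, " at row ",
         which(dt <= 0)[1L] + 1L, call. = FALSE)
  }
  step <- stats::median(dt)
  bad <- which(abs(dt - step) > 1e-4 * step)
  if (length(bad)) {
    stop("non-uniform sampling in ", path, " at row ", bad[1L] + 1L,
         ": step ", dt[bad[1L]], " vs ", step, call. = FALSE)
  }
  structure(list(sampling_rate = 1 / step,
                 time = df$time_s,
                 grip = df$grip_N,
                 load = df$load_N,
                 platform = df$platform_N,
                 photogate = as.logical(df$photogate),
                 true_liftoff_time = NA_real_),
            class = "force_trace")
}

#' Write / read a session manifest
#'
#' @param records List of trial records (as from [simulate_cohort()]); the
#'   `trace_filename` column is filled from `filenames` (or empty).
#' @param path File path (CSV).
#' @param filenames Optional character vector of per-trial trace file names.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns a tibble.
#' @export
write_manifest <- function(records, path, filenames = NULL) {
  df <- data.frame(
    participant_id = vapply(records, `[[`, numeric(1), "participant_id"),
    trial_index = vapply(records, `[[`, numeric(1), "trial_index"),
    label = vapply(records, `[[`, character(1), "cube"),
    mass_g = vapply(records, function(r) r$stimulus$mass, numeric(1)),
    magnitude_estimate = vapply(records, `[[`, numeric(1),
                                "magnitude_estimate"),
    trace_filename = filenames %||% rep("", length(records))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path)
  need <- c("participant_id", "trial_index", "label", "mass_g",
            "magnitude_estimate", "trace_filename")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("manifest ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

# ICC comparison pairs: handle measure vs platform measure
ICC_PAIRS <- list(force_rate_peak = c("PLFR", "PPFR"),
                  force_at_first_peak = c("LF1st", "PF1st"),
                  load_phase_duration = c("LPD1", "LPD2"))

CONDITION_CELLS <- c(heavy_after_heavy = "heavy.no_switch",
                     heavy_after_light = "heavy.switch",
                     light_after_light = "light.no_switch",
                     light_after_heavy = "light.switch")

#' Run the full measurement-and-validation pipeline
#'
#' Simulates a cohort (or ingests one; supply `records`), extracts the nine
#' dependent measures per trial, normalises ratings to %-scores, applies the
#' +/-`trim_k` SD trim at the configured scope, aggregates per-participant
#' condition-cell means, and computes (a) the 2x2 repeated-measures ANOVA
#' and switch contrasts per measure, and (b) handle-vs-platform ICC(3,1)
#' for the force-rate peaks (PLFR vs PPFR), forces at first rate peak
#' (LF1st vs PF1st) and load phase durations (LPD1 vs LPD2), split by the
#' four transition conditions.  Fully deterministic given `config$seed`;
#' every dropped or absent value is logged with its reason.
#'
#' @param config A [sim_config()].
#' @param extraction An [extraction_config()].
#' @param records Optional pre-built list of trial records (each with a
#'   `trace`); when `NULL` the cohort is simulated from `config`.
#' @param out_dir Optional directory: when given, writes `measures.csv`,
#'   `anova.csv`, `contrasts.csv`, `icc.csv`, `dropped.csv` and
#'   `summary.txt` there.
#' @return List with `measures` (trial-level tibble), `cell_means`, `anova`,
#'   `contrasts`, `icc`, `dropped` (log of every absent/trimmed value), and
#'   `notes` (per-measure analyses that could not run, with reasons).
#' @export
run_pipeline <- function(config = sim_config(),
                         extraction = extraction_config(),
                         records = NULL,
                         out_dir = NULL) {
  measures_rows <- list()
  dropped <- list()
  drop_note <- function(participant, trial, measure, reason) {
    dropped[[length(dropped) + 1L]] <<- tibble::tibble(
      participant_id = participant, trial_index = trial,
      measure = measure, reason = reason)
  }

  extract_one <- function(rec) {
    mm <- tryCatch(extract_measures(rec$trace, extraction),
                   error = function(e) {
                     drop_note(rec$participant_id, rec$trial_index, "all",
                               conditionMessage(e))
                     NULL
                   })
    if (!is.null(mm)) {
      ab <- attr(mm, "absences")
      for (i in seq_len(nrow(ab))) {
        drop_note(rec$participant_id, rec$trial_index, ab$measure[i],
                  ab$reason[i])
      }
      measures_rows[[length(measures_rows) + 1L]] <<- tibble::tibble(
        participant_id = rec$participant_id,
        trial_index = rec$trial_index,
        cube = rec$cube, switch = rec$switch,
        magnitude_estimate = rec$magnitude_estimate, mm)
    }
    invisible(NULL)
  }

  if (is.null(records)) {
    simulate_cohort(config, keep_traces = FALSE, on_trial = extract_one)
  } else {
    for (rec in records) extract_one(rec)
  }
  measures <- dplyr::bind_rows(measures_rows)

  # %-scores per participant from all of that participant's estimates
  measures <- measures |>
    dplyr::group_by(dplyr::across(dplyr::all_of("participant_id"))) |>
    dplyr::mutate(pct_score = percent_scores(magnitude_estimate,
                                             extraction$pct_convention)) |>
    dplyr::ungroup()

  long <- tidyr::pivot_longer(
    measures[c("participant_id", "trial_index", "cube", "switch",
               MEASURE_NAMES, "pct_score")],
    cols = dplyr::all_of(c(MEASURE_NAMES, "pct_score")),
    names_to = "measure", values_to = "value")

  analyzable <- long[long$switch != "discard", ]
  trimmed <- apply_trim(analyzable, extraction)
  for (i in which(!trimmed$retained %in% TRUE)) {
    if (is.finite(trimmed$value[i])) {
      drop_note(trimmed$participant_id[i], trimmed$trial_index[i],
                trimmed$measure[i],
                sprintf("outside +/-%g SD (%s scope)", extraction$trim_k,
                        extraction$trim_scope))
    }
  }
  retained <- trimmed[trimmed$retained %in% TRUE | !is.finite(trimmed$value), ]

  notes <- list()
  analysis_note <- function(measure, analysis, reason) {
    notes[[length(notes) + 1L]] <<- tibble::tibble(
      measure = measure, analysis = analysis, reason = reason)
  }

  # per-measure cell means; measures with an empty cell cannot enter the
  # ANOVA (mirrors excluding platform first-peak data for light objects)
  cm_all <- list()
  anova_rows <- list()
  contrast_rows <- list()
  for (meas in unique(retained$measure)) {
    sub <- retained[retained$measure == meas,
                    c("participant_id", "cube", "switch", "measure", "value")]
    cm <- tryCatch(condition_means(sub), error = function(e) {
      analysis_note(meas, "rm_anova", conditionMessage(e))
      NULL
    })
    if (is.null(cm)) next
    cm_all[[meas]] <- cm
    an <- tryCatch(rm_anova_2x2(cm), error = function(e) {
      analysis_note(meas, "rm_anova", conditionMessage(e))
      NULL
    })
    if (is.null(an)) next
    an$measure <- meas
    anova_rows[[meas]] <- an
    sc <- switch_contrasts(cm)
    sc$measure <- meas
    contrast_rows[[meas]] <- sc
  }
  cell_means <- dplyr::bind_rows(cm_all)
  anova <- dplyr::bind_rows(anova_rows)
  contrasts <- dplyr::bind_rows(contrast_rows)

  # handle-vs-platform ICCs on per-participant condition means
  icc_rows <- list()
  for (cmp in names(ICC_PAIRS)) {
    pair <- ICC_PAIRS[[cmp]]
    for (cond in names(CONDITION_CELLS)) {
      cs <- strsplit(CONDITION_CELLS[[cond]], ".", fixed = TRUE)[[1L]]
      sub <- retained[retained$cube == cs[1L] & retained$switch == cs[2L] &
                        retained$measure %in% pair, ]
      wide <- sub |>
        dplyr::group_by(dplyr::across(dplyr::all_of(
          c("participant_id", "measure")))) |>
        dplyr::summarise(value = mean(value, na.rm = TRUE),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "measure", values_from = "value")
      missing_pair <- setdiff(pair, names(wide))
      mat <- if (length(missing_pair)) NULL else as.matrix(wide[pair])
      res <- if (is.null(mat)) {
        simpleError(paste("no data for", paste(missing_pair, collapse = ", ")))
      } else {
        tryCatch(icc_3_1(mat), error = function(e) e)
      }
      if (inherits(res, "error")) {
        analysis_note(paste(pair, collapse = " vs "), paste("icc", cond),
                      conditionMessage(res))
        icc_rows[[length(icc_rows) + 1L]] <- tibble::tibble(
          comparison = cmp, condition = cond, n = if (is.null(mat)) 0L else
            sum(stats::complete.cases(mat)),
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          band = NA_character_, status = conditionMessage(res))
      } else {
        icc_rows[[length(icc_rows) + 1L]] <- tibble::tibble(
          comparison = cmp, condition = cond, n = res$n,
          estimate = res$estimate, ci_low = res$ci_low,
          ci_high = res$ci_high, band = res$band, status = "ok")
      }
    }
  }
  icc <- dplyr::bind_rows(icc_rows)

  result <- list(measures = measures,
                 cell_means = cell_means,
                 anova = anova,
                 contrasts = contrasts,
                 icc = icc,
                 dropped = dplyr::bind_rows(dropped),
                 notes = dplyr::bind_rows(notes))
  if (!is.null(out_dir)) write_reports(result, out_dir)
  result
}

# +/-k SD trim at the configured grouping scope; returns `long` with a
# `retained` column (NA for absent values).
apply_trim <- function(long, extraction) {
  group_cols <- switch(extraction$trim_scope,
    participant_cube = c("participant_id", "measure", "cube"),
    participant_cell = c("participant_id", "measure", "cube", "switch"),
    participant = c("participant_id", "measure"),
    global = "measure")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(retained = if (sum(is.finite(value)) < 2L) {
      ifelse(is.finite(value), TRUE, NA)
    } else {
      trim_outliers(value, extraction$trim_k)
    }) |>
    dplyr::ungroup()
}

write_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$measures, "measures.csv")
  wr(result$anova, "anova.csv")
  wr(result$contrasts, "contrasts.csv")
  wr(result$icc, "icc.csv")
  wr(result$dropped, "dropped.csv")
  if (nrow(result$notes)) wr(result$notes, "notes.csv")

  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Lifting-force validity analysis")
  w("===============================")
  w("")
  w("2x2 repeated-measures ANOVA (cube x switch), per measure:")
  for (meas in unique(result$anova$measure)) {
    an <- result$anova[result$anova$measure == meas, ]
    w("  %s:", meas)
    for (i in seq_len(nrow(an))) {
      if (isTRUE(an$degenerate[i])) {
        w("    %-12s degenerate (zero error variance)", an$effect[i])
      } else {
        w("    %-12s F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f",
          an$effect[i], an$df_num[i], an$df_den[i], an$F[i], an$p[i],
          an$partial_eta_sq[i])
      }
    }
    sc <- result$contrasts[result$contrasts$measure == meas, ]
    for (i in seq_len(nrow(sc))) {
      if (isTRUE(sc$degenerate[i])) {
        w("    %s switch-vs-no-switch: degenerate", sc$cube[i])
      } else {
        w(paste0("    %s switch-vs-no-switch: diff = %.3f, t(%d) = %.2f, ",
                 "Bonferroni p = %.4g, d(%s) = %.2f"),
          sc$cube[i], sc$mean_difference[i], sc$df[i], sc$t[i],
          sc$p_bonferroni[i], sc$d_variant[i], sc$cohens_d[i])
      }
    }
  }
  w("")
  w("Handle vs platform ICC(3,1) by transition condition:")
  for (i in seq_len(nrow(result$icc))) {
    r <- result$icc[i, ]
    if (r$status == "ok") {
      w("  %-22s %-18s ICC = %.2f [%.2f, %.2f] (%s, n = %d)",
        r$comparison, r$condition, r$estimate, r$ci_low, r$ci_high,
        r$band, r$n)
    } else {
      w("  %-22s %-18s insufficient data: %s", r$comparison, r$condition,
        r$status)
    }
  }
  w("")
  w("Dropped/absent values: %d (see dropped.csv)", nrow(result$dropped))
  invisible(NULL)
}
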