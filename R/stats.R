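# Inferential layer: ICC(3,1) with exact-F confidence bounds, 2x2
# repeated-measures ANOVA via orthogonal within-subject contrasts, paired
# switch contrasts with Bonferroni correction, and Cohen's d.

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, *consistency* intraclass
#' correlation for comparing two fixed measurement methods applied to the
#' same targets.  From the two-way ANOVA decomposition with row (target)
#' mean square MSR and residual MSE, the estimate is
#' \deqn{ICC = (MSR - MSE) / (MSR + (k - 1) MSE),\quad k = 2,}
#' with the 95% confidence interval from the exact F bounds on MSR/MSE
#' (McGraw-Wong form for the consistency ICC): with
#' `F = MSR/MSE` on (n-1, (n-1)(k-1)) degrees of freedom,
#' `FL = F / qf(.975, n-1, (n-1)(k-1))` and
#' `FU = F * qf(.975, (n-1)(k-1), n-1)`, the bounds are
#' `(F* - 1)/(F* + k - 1)`.  Being a consistency coefficient it is invariant
#' to adding a constant to either column.
#'
#' @param ratings Matrix or data frame with n rows (targets, e.g.
#'   participants) and 2 columns (methods).  Rows containing any missing
#'   value are dropped first.
#' @param conf_level Confidence level (default 0.95).
#' @param type `"consistency"` (ICC(3,1), default) or `"agreement"`
#'   (ICC(A,1), absolute agreement) for sensitivity analysis.
#' @return An `icc_result` list: `estimate`, `ci_low`, `ci_high`, `band`
#'   (Koo-Li label of the estimate), `n`, `type`.
#' @export
icc_3_1 <- function(ratings, conf_level = 0.95,
                    type = c("consistency", "agreement")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (ncol(x) != 2L) stop("`ratings` must have exactly 2 columns",
                          call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- 2L
  if (n < 5L) {
    stop("insufficient data: need at least 5 complete pairs, got ", n,
         call. = FALSE)
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) {
    stop("undefined ICC: the ratings have zero total variance",
         call. = FALSE)
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    # ICC(A,1), McGraw-Wong: column variance enters the denominator
    est <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_up <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(ci_low, ci_up)
  }
  structure(list(estimate = est,
                 ci_low = min(ci[1], est),
                 ci_high = max(ci[2], est),
                 band = interpret_icc(est),
                 n = n, type = type,
                 conf_level = conf_level),
            class = "icc_result")
}

#' Koo-Li interpretation band for an ICC estimate
#'
#' Bins: poor (< .50), moderate (.50-.75), good (.75-.90), excellent
#' (> .90).  The quoted ranges overlap at their endpoints; by default a
#' boundary value falls in the lower band (closed upper edge), e.g. .75 is
#' `moderate`.
#'
#' @param estimate Finite ICC estimate.
#' @param boundary `"lower"` (default) or `"upper"`: which band claims a
#'   boundary value.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @examples
#' interpret_icc(0.87)  # "good"
#' @export
interpret_icc <- function(estimate, boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  stopifnot(is.finite(estimate))
  cuts <- c(0.50, 0.75, 0.90)
  bands <- c("poor", "moderate", "good", "excellent")
  i <- if (boundary == "lower") {
    sum(estimate > cuts)
  } else {
    sum(estimate >= cuts)
  }
  bands[i + 1L]
}

# Reshape a long cell-mean table for one measure into the per-participant
# 2x2 matrix [light_no_switch, light_switch, heavy_no_switch, heavy_switch].
cell_matrix <- function(cell_means) {
  stopifnot(all(c("participant_id", "cube", "switch", "mean")
                %in% names(cell_means)))
  wide <- tidyr::pivot_wider(
    cell_means[c("participant_id", "cube", "switch", "mean")],
    names_from = c("cube", "switch"), values_from = "mean"
  )
  cols <- c("light_no_switch", "light_switch",
            "heavy_no_switch", "heavy_switch")
  if (!all(cols %in% names(wide)) ||
      anyNA(wide[cols])) {
    stop("incomplete 2x2 cell table: every participant needs all four ",
         "(cube, switch) cell means", call. = FALSE)
  }
  m <- as.matrix(wide[cols])
  rownames(m) <- wide$participant_id
  m
}

#' 2x2 repeated-measures ANOVA
#'
#' Within-subject ANOVA for the 2 (cube: light/heavy) x 2 (switch:
#' switch/no-switch) design, computed from the orthogonal per-participant
#' contrasts.  With two-level factors each effect has 1 numerator df, its own
#' error term with n - 1 df, `F = t^2` for the corresponding contrast t, and
#' sphericity holds trivially.  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` for the effect's own error term.
#'
#' @param cell_means Long tibble for one measure with columns
#'   `participant_id`, `cube`, `switch`, `mean` (one row per participant x
#'   cell), e.g. one measure's slice of [condition_means()] output.
#' @return An `anova_result` tibble with one row per effect (`cube`,
#'   `switch`, `interaction`): `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `degenerate`.  A zero-variance contrast yields a
#'   degenerate row (`NA` statistics, `degenerate = TRUE`) rather than an
#'   error.
#' @export
rm_anova_2x2 <- function(cell_means) {
  m <- cell_matrix(cell_means)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  # columns: light_ns, light_s, heavy_ns, heavy_s
  contrasts <- list(
    cube = c(-1, -1, 1, 1) / 2,
    switch = c(-1, 1, -1, 1) / 2,
    interaction = c(1, -1, -1, 1) / 2
  )
  rows <- lapply(names(contrasts), function(nm) {
    ci <- as.numeric(m %*% contrasts[[nm]])
    s <- stats::sd(ci)
    if (!is.finite(s) || s == 0) {
      return(tibble::tibble(effect = nm, F = NA_real_, df_num = 1L,
                            df_den = n - 1L, p = NA_real_,
                            partial_eta_sq = NA_real_, degenerate = TRUE))
    }
    tval <- mean(ci) / (s / sqrt(n))
    Fval <- tval^2
    tibble::tibble(effect = nm, F = Fval, df_num = 1L, df_den = n - 1L,
                   p = stats::pf(Fval, 1, n - 1, lower.tail = FALSE),
                   partial_eta_sq = Fval / (Fval + n - 1),
                   degenerate = FALSE)
  })
  structure(dplyr::bind_rows(rows), class = c("anova_result",
                                              class(tibble::tibble())))
}

#' Switch vs no-switch post-hoc contrasts
#'
#' Paired t-tests of the switch vs no-switch cell means within each cube
#' level, Bonferroni-corrected for the contrast family (default family size
#' 2: one contrast per cube), with Cohen's d.
#'
#' @param cell_means As in [rm_anova_2x2()].
#' @param correction_family_size Bonferroni multiplier (default 2).
#' @param d_variant Cohen's d standardizer passed to [cohens_d()].
#' @return Tibble with one row per cube: `cube`, `mean_difference` (switch
#'   minus no-switch), `t`, `df`, `p`, `p_bonferroni`, `cohens_d`,
#'   `d_variant`, `degenerate`.
#' @export
switch_contrasts <- function(cell_means, correction_family_size = 2,
                             d_variant = c("dz", "dav")) {
  d_variant <- match.arg(d_variant)
  m <- cell_matrix(cell_means)
  n <- nrow(m)
  out <- lapply(c("heavy", "light"), function(cube) {
    a <- m[, paste0(cube, "_switch")]
    b <- m[, paste0(cube, "_no_switch")]
    diff <- a - b
    s <- stats::sd(diff)
    if (!is.finite(s) || s == 0) {
      return(tibble::tibble(cube = cube, mean_difference = mean(diff),
                            t = NA_real_, df = n - 1L, p = NA_real_,
                            p_bonferroni = NA_real_, cohens_d = NA_real_,
                            d_variant = d_variant, degenerate = TRUE))
    }
    tval <- mean(diff) / (s / sqrt(n))
    p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
    d <- cohens_d(a, b, variant = d_variant)
    tibble::tibble(cube = cube, mean_difference = mean(diff), t = tval,
                   df = n - 1L, p = p,
                   p_bonferroni = min(1, p * correction_family_size),
                   cohens_d = d$d, d_variant = d_variant,
                   degenerate = FALSE)
  })
  dplyr::bind_rows(out)
}

#' Cohen's d for paired data
#'
#' `dz` standardizes the mean difference by the SD of the differences;
#' `dav` standardizes by the average of the two condition SDs.  The variant
#' is always recorded alongside the value since the two can differ
#' substantially for highly correlated pairs.
#'
#' @param a Either a vector of paired differences, or the first condition's
#'   values when `b` is supplied.
#' @param b Optional second condition (paired with `a`).
#' @param variant `"dz"` (default) or `"dav"` (`dav` requires both
#'   conditions).
#' @return List with `d`, `variant`, `degenerate` (`TRUE` with `d = NA` when
#'   the standardizer is zero).
#' @export
cohens_d <- function(a, b = NULL, variant = c("dz", "dav")) {
  variant <- match.arg(variant)
  if (is.null(b)) {
    if (variant == "dav") {
      stop("`dav` needs both paired columns, not bare differences",
           call. = FALSE)
    }
    diff <- a
  } else {
    stopifnot(length(a) == length(b))
    diff <- a - b
  }
  if (length(diff) < 2L) stop("need at least 2 pairs", call. = FALSE)
  denom <- if (variant == "dz") {
    stats::sd(diff)
  } else {
    (stats::sd(a) + stats::sd(b)) / 2
  }
  if (!is.finite(denom) || denom == 0) {
    return(list(d = NA_real_, variant = variant, degenerate = TRUE))
  }
  list(d = mean(diff) / denom, variant = variant, degenerate = FALSE)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.3f, %d%% CI [%.3f, %.3f], %s agreement (n = %d)\n",
              if (x$type == "consistency") "3" else "A",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$band, x$n))
  invisible(x)
}
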