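test_that("ICC(3,1) honours its defining consistency properties", {
  withr::with_seed(42, {
    row_eff <- stats::rnorm(8, 0, 3)
    x <- cbind(row_eff + stats::rnorm(8), row_eff + stats::rnorm(8))
  })
  expect_equal(icc_3_1(cbind(x[, 1], x[, 1]))$estimate, 1)
  # additive method offset is invisible to the consistency form
  expect_equal(icc_3_1(cbind(x[, 1], x[, 1] + 5))$estimate, 1)
  r <- icc_3_1(x)
  expect_equal(icc_3_1(x + 100)$estimate, r$estimate)
  expect_equal(icc_3_1(x[sample(8), ])$estimate, r$estimate)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("ICC(3,1) matches an independent two-way ANOVA decomposition", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 6 + seed
      row_eff <- stats::rnorm(n, 0, 2)
      x <- cbind(row_eff + stats::rnorm(n), 0.5 + row_eff + stats::rnorm(n))
    })
    long <- data.frame(v = c(x), row = factor(rep(seq_len(nrow(x)), 2)),
                       col = factor(rep(1:2, each = nrow(x))))
    ms <- summary(stats::aov(v ~ row + col, long))[[1]][, "Mean Sq"]
    oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
    expect_equal(icc_3_1(x)$estimate, oracle, tolerance = 1e-6)
  }
})

test_that("ICC confidence bounds follow the exact F construction", {
  withr::with_seed(10, {
    row_eff <- stats::rnorm(12, 0, 2)
    x <- cbind(row_eff + stats::rnorm(12), row_eff + stats::rnorm(12))
  })
  r <- icc_3_1(x)
  n <- 12; k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  mse <- (sum((x - grand)^2) - k * sum((rowMeans(x) - grand)^2) -
            n * sum((colMeans(x) - grand)^2)) / ((n - 1) * (k - 1))
  fobs <- msr / mse
  fl <- fobs / stats::qf(0.975, n - 1, n - 1)
  fu <- fobs * stats::qf(0.975, n - 1, n - 1)
  expect_equal(r$ci_low, (fl - 1) / (fl + 1), tolerance = 1e-12)
  expect_equal(r$ci_high, (fu - 1) / (fu + 1), tolerance = 1e-12)
})

test_that("ICC guards degenerate inputs", {
  expect_error(icc_3_1(cbind(1:4, 1:4)), "at least 5")
  expect_error(icc_3_1(matrix(3, 6, 2)), "zero total variance")
  # rows with missing values are dropped before the n >= 5 check
  x <- cbind(c(1:5, NA), c(2:6, 1))
  expect_error(icc_3_1(x[-1, ]), "at least 5")
})

test_that("Koo-Li bands bin estimates with closed lower-band boundaries", {
  expect_equal(interpret_icc(0.49), "poor")
  expect_equal(interpret_icc(0.87), "good")
  expect_equal(interpret_icc(0.98), "excellent")
  expect_equal(interpret_icc(0.65), "moderate")
  # boundaries fall in the lower band by default, upper on request
  expect_equal(interpret_icc(0.75), "moderate")
  expect_equal(interpret_icc(0.90), "good")
  expect_equal(interpret_icc(0.50), "poor")
  expect_equal(interpret_icc(0.75, boundary = "upper"), "good")
})

test_that("the 2x2 RM-ANOVA matches the sum-of-squares oracle to 6 decimals", {
  for (seed in c(1, 7, 23)) {
    cm <- random_cell_means(8, seed = seed)
    res <- rm_anova_2x2(cm)
    o <- anova_ss_oracle(cm)
    for (eff in c("cube", "switch", "interaction")) {
      row <- res[res$effect == eff, ]
      expect_equal(row$F, unname(o$F[eff]), tolerance = 1e-6)
      expect_equal(row$partial_eta_sq, unname(o$partial_eta_sq[eff]),
                   tolerance = 1e-6)
      expect_equal(row$df_den, o$df_den)
      expect_equal(row$p,
                   stats::pf(o$F[[eff]], 1, o$df_den, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
})

test_that("each ANOVA F equals the squared within-subject contrast t", {
  for (seed in 1:10) {
    cm <- random_cell_means(6 + seed %% 4, seed = 100 + seed)
    res <- rm_anova_2x2(cm)
    wide <- tidyr::pivot_wider(cm, names_from = c("cube", "switch"),
                               values_from = "mean")
    contr <- list(
      cube = (wide$heavy_no_switch + wide$heavy_switch -
                wide$light_no_switch - wide$light_switch) / 2,
      switch = (wide$light_switch + wide$heavy_switch -
                  wide$light_no_switch - wide$heavy_no_switch) / 2,
      interaction = (wide$heavy_switch - wide$heavy_no_switch -
                       wide$light_switch + wide$light_no_switch) / 2
    )
    for (eff in names(contr)) {
      tval <- stats::t.test(contr[[eff]])$statistic
      expect_equal(res$F[res$effect == eff], unname(tval^2),
                   tolerance = 1e-10)
    }
  }
})

test_that("an interaction-only pattern isolates the interaction effect", {
  withr::with_seed(3, {
    n <- 12
    d <- 2
    cm <- expand.grid(participant_id = seq_len(n),
                      cube = c("light", "heavy"),
                      switch = c("no_switch", "switch"),
                      stringsAsFactors = FALSE)
    sign <- ifelse(cm$cube == "light", 1, -1) *
      ifelse(cm$switch == "no_switch", 1, -1)
    cm$mean <- d * sign + stats::rnorm(nrow(cm), 0, 0.05)
  })
  res <- rm_anova_2x2(cm)
  expect_gt(res$F[res$effect == "interaction"], 1000)
  expect_lt(res$F[res$effect == "cube"], 10)
  expect_lt(res$F[res$effect == "switch"], 10)
})

test_that("zero-variance cells give a degenerate result, not a crash", {
  cm <- expand.grid(participant_id = 1:5,
                    cube = c("light", "heavy"),
                    switch = c("no_switch", "switch"),
                    stringsAsFactors = FALSE)
  cm$mean <- 1
  res <- rm_anova_2x2(cm)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$F)))
  sc <- switch_contrasts(cm)
  expect_true(all(sc$degenerate))
  expect_equal(sc$mean_difference, c(0, 0))
})

test_that("ANOVA input validation catches incomplete tables", {
  cm <- random_cell_means(6, seed = 2)
  expect_error(rm_anova_2x2(cm[-1, ]), "incomplete")
  expect_error(rm_anova_2x2(random_cell_means(2, seed = 1)), "at least 3")
})

test_that("switch contrasts match a textbook paired t computation", {
  cm <- random_cell_means(29, seed = 77)
  sc <- switch_contrasts(cm)
  for (cube in c("heavy", "light")) {
    a <- cm$mean[cm$cube == cube & cm$switch == "switch"]
    b <- cm$mean[cm$cube == cube & cm$switch == "no_switch"]
    tt <- stats::t.test(a, b, paired = TRUE)
    row <- sc[sc$cube == cube, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_bonferroni, min(1, 2 * tt$p.value), tolerance = 1e-12)
    expect_equal(row$mean_difference, mean(a - b))
    expect_equal(row$cohens_d, mean(a - b) / stats::sd(a - b),
                 tolerance = 1e-12)
  }
})

test_that("identical columns give a null contrast with corrected p = 1", {
  cm <- random_cell_means(10, seed = 5)
  cm$mean[cm$switch == "switch"] <-
    cm$mean[cm$switch == "no_switch"]
  sc <- switch_contrasts(cm)
  expect_true(all(sc$degenerate))
  expect_equal(sc$mean_difference, c(0, 0))
})

test_that("Cohen's d variants match direct formula evaluation", {
  expect_equal(cohens_d(c(-1, 0, 1))$d, 0)
  expect_true(cohens_d(rep(2, 5))$degenerate)
  withr::with_seed(8, {
    a <- stats::rnorm(20, 1)
    b <- stats::rnorm(20)
  })
  dz <- cohens_d(a, b, variant = "dz")
  expect_equal(dz$d, mean(a - b) / stats::sd(a - b))
  dav <- cohens_d(a, b, variant = "dav")
  expect_equal(dav$d, mean(a - b) / ((stats::sd(a) + stats::sd(b)) / 2))
  expect_error(cohens_d(a - b, variant = "dav"), "both paired columns")
})

test_that("null 2x2 data reject the interaction at the nominal 5% rate", {
  n_sim <- 400
  reject <- withr::with_seed(2024, vapply(seq_len(n_sim), function(i) {
    cm <- expand.grid(participant_id = 1:29,
                      cube = c("light", "heavy"),
                      switch = c("no_switch", "switch"),
                      stringsAsFactors = FALSE)
    cm$mean <- stats::rnorm(nrow(cm))
    rm_anova_2x2(cm)$p[3] < 0.05
  }, logical(1)))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})
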