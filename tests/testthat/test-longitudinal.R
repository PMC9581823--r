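test_that("delta scores are follow-up minus baseline and antisymmetric", {
  cohort <- data.frame(participant_id = c("P1", "P2", "P3"),
                       group = c("NC", "NC", "BCC_PLUS"),
                       dmn_bl = c(0.30, 0.42, NA),
                       dmn_fu = c(0.35, 0.42, 0.50))
  expect_message(d <- delta_scores(cohort, "DMN_dFC"), "P3")
  expect_equal(d$delta, c(0.05, 0))
  swapped <- cohort
  swapped$dmn_bl <- cohort$dmn_fu
  swapped$dmn_fu <- cohort$dmn_bl
  suppressMessages(
    expect_equal(delta_scores(swapped, "DMN_dFC")$delta, -d$delta))
})

test_that("repeated-measures ANOVA agrees with the aov error-strata oracle", {
  # 12-subject fixture, balanced groups, random two-timepoint data
  set.seed(12)
  group <- factor(rep(c("BCC_PLUS", "BCC_MINUS", "NC"), each = 4),
                  levels = c("BCC_PLUS", "BCC_MINUS", "NC"))
  y_bl <- rnorm(12)
  y_fu <- rnorm(12)
  got <- rm_ancova_fit(y_bl, y_fu, group)

  long <- data.frame(y = c(y_bl, y_fu),
                     time = factor(rep(c("bl", "fu"), each = 12)),
                     subject = factor(rep(1:12, 2)),
                     group = rep(group, 2))
  fit <- summary(stats::aov(y ~ group * time + Error(subject), data = long))
  between <- fit[["Error: subject"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  expect_equal(got$f_value[got$term == "group"], between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(got$f_value[got$term == "time"], within["time", "F value"],
               tolerance = 1e-8)
  expect_equal(got$f_value[got$term == "group:time"],
               within["group:time", "F value"], tolerance = 1e-8)
  expect_equal(got$df_den[got$term == "group"],
               between["Residuals", "Df"])
  expect_equal(got$df_den[got$term == "time"], within["Residuals", "Df"])
})

test_that("degenerate and ground-truth designs behave as expected", {
  # no change, no group structure: all F zero, nothing significant
  cohort <- data.frame(participant_id = sprintf("P%02d", 1:12),
                       group = rep(c("BCC_PLUS", "BCC_MINUS", "NC"), 4),
                       dmn_bl = rep(0.4, 12), dmn_fu = rep(0.4, 12))
  res <- mixed_anova_dfc(cohort, "DMN_dFC")
  expect_true(all(res$f_value == 0))
  expect_false(any(res$significant))

  # a pure time shift of 0.5 SD at n = 90 is detected; group terms are not
  set.seed(90)
  n <- 90
  bl <- rnorm(n, 0.5, 0.1)
  noise <- rnorm(n, 0, 0.1)
  noise <- noise - mean(noise)     # realized shift exactly 0.5 SD of change
  shift_cohort <- data.frame(
    participant_id = sprintf("P%02d", 1:n),
    group = rep(c("BCC_PLUS", "BCC_MINUS", "NC"), each = 30),
    dmn_bl = bl, dmn_fu = bl + 0.05 + noise)
  res2 <- mixed_anova_dfc(shift_cohort, "DMN_dFC")
  expect_true(res2$significant[res2$term == "time"])
  expect_false(res2$significant[res2$term == "group"])
  expect_false(res2$significant[res2$term == "group:time"])

  small <- cohort[c(1:2, 3:4, 5:12), ]
  small$group <- c("BCC_PLUS", "BCC_PLUS", rep(c("BCC_MINUS", "NC"), 5))
  expect_error(mixed_anova_dfc(small, "DMN_dFC"), "fewer than 3")
})

test_that("Type-III ANCOVA terms match the car oracle on an unbalanced fixture", {
  df <- analytic_cohort(n_per_group = c(9, 7, 11),
                        slopes = c(0.5, -0.3, 0.1),
                        time_shift = 0.2, beta_age = -0.02, seed = 77)
  got <- rm_ancova_fit(df$y_bl, df$y_fu, df$group, delta = df$delta,
                       covariates = df[, c("age", "iq")])

  m <- (df$y_bl + df$y_fu) / 2
  d <- df$y_fu - df$y_bl
  dat <- data.frame(m = m, d = d, group = df$group,
                    delta_c = df$delta - mean(df$delta),
                    age_c = df$age - mean(df$age),
                    iq_c = df$iq - mean(df$iq))
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts), add = TRUE)
  oracle_between <- car::Anova(lm(m ~ group * delta_c + age_c + iq_c,
                                  data = dat), type = 3)
  oracle_within <- car::Anova(lm(d ~ group * delta_c + age_c + iq_c,
                                 data = dat), type = 3)

  pick <- function(res, term) res$f_value[res$term == term]
  expect_equal(pick(got, "group"), oracle_between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "dfc_change"), oracle_between["delta_c", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "group:dfc_change"),
               oracle_between["group:delta_c", "F value"], tolerance = 1e-8)
  expect_equal(pick(got, "age"), oracle_between["age_c", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "iq"), oracle_between["iq_c", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "time"), oracle_within["(Intercept)", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "group:time"), oracle_within["group", "F value"],
               tolerance = 1e-8)
  expect_equal(pick(got, "dfc_change:time"),
               oracle_within["delta_c", "F value"], tolerance = 1e-8)
  expect_equal(pick(got, "group:dfc_change:time"),
               oracle_within["group:delta_c", "F value"], tolerance = 1e-8)
})

test_that("ANCOVA nests the repeated-measures ANOVA and respects invariances", {
  df <- analytic_cohort(seed = 5)
  full <- rm_ancova_fit(df$y_bl, df$y_fu, df$group)
  plain <- rm_ancova_fit(df$y_bl, df$y_fu, df$group, delta = NULL,
                         covariates = NULL)
  expect_equal(full, plain, tolerance = 1e-8)

  # residual df of the two error strata: (n - p) each
  withcov <- rm_ancova_fit(df$y_bl, df$y_fu, df$group, delta = df$delta,
                           covariates = df[, c("age", "iq")])
  expect_true(all(withcov$df_den == nrow(df) - 8))

  # affine rescaling of covariates leaves every F unchanged
  rescaled <- rm_ancova_fit(df$y_bl, df$y_fu, df$group, delta = df$delta,
                            covariates = data.frame(age = 12 * df$age - 300,
                                                    iq = df$iq / 10 + 2))
  expect_equal(withcov$f_value, rescaled$f_value, tolerance = 1e-8)

  # permutation invariance of participant order
  perm <- sample(nrow(df))
  permuted <- rm_ancova_fit(df$y_bl[perm], df$y_fu[perm], df$group[perm],
                            delta = df$delta[perm],
                            covariates = df[perm, c("age", "iq")])
  expect_equal(withcov$f_value, permuted$f_value, tolerance = 1e-10)

  # constant continuous predictor is reported as aliased
  expect_error(rm_ancova_fit(df$y_bl, df$y_fu, df$group,
                             delta = rep(1, nrow(df))),
               "dfc_change")

  # boundary significance: p exactly at alpha is not significant
  res <- model_result("x", f = 1, df_num = 1, df_den = 10, p = 0.01,
                      alpha = 0.01)
  expect_false(res$significant)
})

test_that("cohort-level ANCOVA wrapper reports results and per-group slopes", {
  cfg <- sim_config(seed = 44,
                    modulation_depth = matrix(c(0.15, 0.15, 0.15,
                                                0.25, 0.25, 0.25), 3, 2),
                    cognitive = list(slope = c(BCC_PLUS = -2, BCC_MINUS = 2,
                                               NC = -2), noise_sd = 0.2))
  sim <- simulate_cohort(cfg, timeseries = "none")
  fit <- rm_ancova(sim$cohort, ancova_spec("HVLT_IR"))
  expect_setequal(fit$results$term,
                  c("group", "dfc_change", "group:dfc_change", "age", "iq",
                    "time", "group:time", "dfc_change:time",
                    "group:dfc_change:time"))
  expect_equal(fit$n, 101)
  # slope-inhomogeneity sign pattern: positive for untreated patients only
  expect_gt(fit$slopes[["BCC_MINUS"]], 0)
  expect_lt(fit$slopes[["BCC_PLUS"]], 0)
  expect_lt(fit$slopes[["NC"]], 0)
})
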