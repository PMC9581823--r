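test_that("z-standardization anchors to the norm group with the TMT-B sign flip", {
  anchors <- list(mean = 50, sd = 5)
  expect_equal(zscore(50, "HVLT_IR", anchors), 0)
  expect_equal(zscore(55, "HVLT_IR", anchors), 1.0)
  # more seconds than the norm mean = worse performance = negative z
  expect_lt(zscore(60, "TMTB", anchors), 0)
  expect_equal(zscore(45, "TMTB", anchors), 1.0)
  # affine equivariance: shifting raw scores and the anchor together
  expect_equal(zscore(55 + 3, "HVLT_IR", list(mean = 53, sd = 5)),
               zscore(55, "HVLT_IR", anchors))
  expect_error(zscore(1, "WAIS", anchors))
})

test_that("norm regression recovers known coefficients and centers residuals", {
  # noiseless norm group generated from known coefficients
  set.seed(21)
  n <- 40
  age <- rnorm(n, 50, 9)
  iq <- rnorm(n, 104, 13)
  hvlt_bl <- rnorm(n, 25, 5)
  anchors <- list(mean = mean(hvlt_bl), sd = sd(hvlt_bl))
  bl_z <- zscore(hvlt_bl, "HVLT_IR", anchors)
  truth <- c(intercept = 0.3, baseline_z = 0.6, age = -0.01, iq = 0.005)
  fu_z <- truth[1] + truth[2] * bl_z + truth[3] * age + truth[4] * iq
  cohort <- data.frame(participant_id = sprintf("S%02d", 1:n), group = "NC",
                       age = age, iq = iq,
                       hvlt_bl = hvlt_bl,
                       hvlt_fu = anchors$mean + anchors$sd * fu_z,
                       tmtb_bl = 60, tmtb_fu = 60)
  norm <- fit_norm_regression(cohort, "HVLT_IR")
  expect_equal(unname(norm$coef), unname(truth), tolerance = 1e-8)
  expect_equal(norm$n, n)

  # with noise: residuals of the norm group average to zero (OLS property)
  cohort$hvlt_fu <- cohort$hvlt_fu + rnorm(n, 0, 3)
  norm2 <- fit_norm_regression(cohort, "HVLT_IR")
  rs <- residual_scores(cohort, norm2, "HVLT_IR")
  expect_equal(mean(rs$residual), 0, tolerance = 1e-10)
  expect_equal(rs$residual, rs$followup_z - rs$predicted)

  expect_error(fit_norm_regression(cohort[1:4, ], "HVLT_IR"), "too few")
})

test_that("coefficient estimates improve with norm-group size", {
  rmse_at_n <- function(n) {
    errs <- sapply(1:25, function(rep) {
      set.seed(1000 * n + rep)
      age <- rnorm(n, 50, 9); iq <- rnorm(n, 104, 13)
      hvlt_bl <- rnorm(n, 25, 5)
      anchors <- list(mean = mean(hvlt_bl), sd = sd(hvlt_bl))
      fu_z <- 0.2 + 0.5 * zscore(hvlt_bl, "HVLT_IR", anchors) -
        0.01 * age + 0.005 * iq + rnorm(n, 0, 0.8)
      cohort <- data.frame(participant_id = seq_len(n), group = "NC",
                           age = age, iq = iq, hvlt_bl = hvlt_bl,
                           hvlt_fu = anchors$mean + anchors$sd * fu_z,
                           tmtb_bl = 60, tmtb_fu = 60)
      norm <- fit_norm_regression(cohort, "HVLT_IR")
      sqrt(mean((norm$coef - c(0.2, 0.5, -0.01, 0.005))^2))
    })
    mean(errs)
  }
  rmses <- sapply(c(40, 100, 400), rmse_at_n)
  expect_true(all(diff(rmses) < 0))
})

test_that("residual scores follow the prediction equation on a hand fixture", {
  norm <- norm_model("HVLT_IR", mean = 25, sd = 5,
                     coef = c(intercept = 0.1, baseline_z = 0.5,
                              age = -0.002, iq = 0.001), n = 37)
  cohort <- data.frame(participant_id = "P1", group = "BCC_PLUS",
                       age = 50, iq = 100,
                       hvlt_bl = 27, hvlt_fu = 27.2,
                       tmtb_bl = 60, tmtb_fu = 60)
  rs <- residual_scores(cohort, norm, "HVLT_IR")
  pred_hand <- 0.1 + 0.5 * (27 - 25) / 5 - 0.002 * 50 + 0.001 * 100
  expect_equal(rs$predicted, pred_hand)              # = 0.30
  expect_equal(rs$followup_z, 0.44)
  expect_equal(rs$residual, 0.44 - 0.30, tolerance = 1e-12)

  # missing covariate: participant excluded with a message
  cohort2 <- rbind(cohort,
                   data.frame(participant_id = "P2", group = "NC",
                              age = NA, iq = 100, hvlt_bl = 25,
                              hvlt_fu = 25, tmtb_bl = 60, tmtb_fu = 60))
  expect_message(rs2 <- residual_scores(cohort2, norm, "HVLT_IR"), "P2")
  expect_equal(nrow(rs2), 1)
})

test_that("one-way ANOVA matches explicit sums of squares and is calibrated", {
  vals <- c(2, 4, 4, 6, 6, 8)
  grp <- rep(c("a", "b", "c"), each = 2)
  res <- oneway_anova(vals, grp)
  oracle <- oneway_oracle(vals, grp)
  expect_equal(res$f_value, oracle$f, tolerance = 1e-12)
  expect_equal(res$f_value, 4)               # hand computation
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 3L)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)

  expect_equal(oneway_anova(rep(5, 9), rep(c("a", "b", "c"), 3))$f_value, 0)
  expect_error(oneway_anova(1:3, c("a", "a", "b")), "fewer than 2")

  # null calibration at alpha = 0.05 over 1000 replicates
  set.seed(30)
  rejections <- sum(replicate(1000, {
    oneway_anova(rnorm(30), rep(c("a", "b", "c"), each = 10),
                 alpha = 0.05)$significant
  }))
  bounds <- exact_binomial_bounds(1000, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("pooled effect size reproduces the published memory comparison", {
  # group summaries for chemotherapy patients vs controls on memory change
  es <- pooled_effect_size(-0.07, 0.89, 34, -0.01, 0.97, 35)
  expect_equal(round_half_away(es, 2), -0.06)
  # antisymmetry and closed-form cases
  expect_equal(pooled_effect_size(-0.01, 0.97, 35, -0.07, 0.89, 34), -es)
  expect_equal(pooled_effect_size(1, 1, 10, 0, 1, 10), 1.0)
  expect_equal(pooled_effect_size(0.4, 0.9, 12, 0.4, 1.2, 15), 0)
  expect_error(pooled_effect_size(1, 1, 1, 0, 1, 10), "n >= 2")
  expect_error(pooled_effect_size(1, 0, 10, 0, 1, 10), "positive")
})

test_that("cognition summary assembles group means, effect sizes and ANOVA", {
  sim <- simulate_cohort(sim_config(seed = 33), timeseries = "none")
  norm <- fit_norm_regression(sim$cohort, "HVLT_IR")
  summ <- cognition_summary(sim$cohort, norm, "HVLT_IR")
  expect_setequal(summ$summary$group, c("BCC_PLUS", "BCC_MINUS", "NC"))
  expect_equal(sum(summ$summary$n), 101)
  a <- summ$summary[summ$summary$group == "BCC_PLUS", ]
  b <- summ$summary[summ$summary$group == "NC", ]
  expect_equal(unname(summ$effect_sizes["NC"]),
               pooled_effect_size(a$mean, a$sd, a$n, b$mean, b$sd, b$n))
  expect_s3_class(summ$anova, "data.frame")

  # head-motion group comparison runs through the same one-way ANOVA
  motion <- oneway_anova(sim$cohort$motion_bl, sim$cohort$group)
  expect_equal(motion$df_num, 2L)
  expect_equal(motion$df_den, 98L)
})
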