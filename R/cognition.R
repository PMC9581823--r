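#' Neuropsychological tests handled by the pipeline
#'
#' `HVLT_IR` is Hopkins Verbal Learning Test–Revised immediate recall
#' (words recalled, higher is better; memory measure). `TMTB` is Trail
#' Making Test part B (completion time in seconds, higher is worse;
#' executive-function measure).
#' @keywords internal
COGNITIVE_TESTS <- c("HVLT_IR", "TMTB")

test_prefix <- function(test) {
  switch(test, HVLT_IR = "hvlt", TMTB = "tmtb",
         stop("unknown test label: ", test, call. = FALSE))
}

#' Normative standardization model
#'
#' Bundles, for one test, the z-score anchors (raw mean and SD of the
#' normative control group at baseline) and the coefficients of the
#' norm-group regression predicting follow-up z from baseline z, age and
#' IQ. Fitted by [fit_norm_regression()].
#'
#' @param test Test label, `"HVLT_IR"` or `"TMTB"`.
#' @param mean,sd Raw-score mean and SD of the norm group at baseline.
#' @param coef Named numeric vector `(intercept, baseline_z, age, iq)`.
#' @param n Norm-group size used for the fit.
#' @return A `dynfc_norm_model` object.
#' @export
norm_model <- function(test, mean, sd, coef, n) {
  test <- match.arg(test, COGNITIVE_TESTS)
  if (!is.finite(sd) || sd <= 0) stop("norm SD must be positive", call. = FALSE)
  if (any(!is.finite(coef))) stop("non-finite regression coefficients", call. = FALSE)
  structure(list(test = test, mean = mean, sd = sd,
                 coef = coef, n = as.integer(n)),
            class = "dynfc_norm_model")
}

#' Standardized z-score against the normative group
#'
#' `z = (raw - norm mean) / norm SD` for HVLT-R immediate recall. For
#' TMT-B, where more seconds mean worse performance, the sign is flipped at
#' standardization time (`z = -(raw - mean)/sd`) so that lower z uniformly
#' means worse performance across tests; raw seconds are never compared
#' across tests.
#'
#' @param raw Raw test score(s).
#' @param test `"HVLT_IR"` or `"TMTB"`.
#' @param norm A `dynfc_norm_model` (or any list with `mean` and `sd`)
#'   providing the anchors.
#' @return Numeric z-score(s).
#' @export
zscore <- function(raw, test = c("HVLT_IR", "TMTB"), norm) {
  test <- match.arg(test)
  z <- (raw - norm$mean) / norm$sd
  if (test == "TMTB") -z else z
}

#' Fit the norm-group change regression
#'
#' Computes z-score anchors from the norm group's baseline raw scores,
#' standardizes both timepoints, and fits an ordinary least-squares
#' regression of follow-up z on baseline z, age and IQ (with intercept) in
#' the norm group only. Applied to the whole cohort by
#' [residual_scores()], this yields regression-based normative change
#' scores: follow-up performance corrected for baseline, age and IQ.
#'
#' @param norm_cohort Cohort table restricted to (or filtered here to) the
#'   normative group.
#' @param test Test label.
#' @param group Norm group label (default `"NC"`); rows of other groups are
#'   dropped before fitting.
#' @return A `dynfc_norm_model`.
#' @export
fit_norm_regression <- function(norm_cohort, test = c("HVLT_IR", "TMTB"),
                                group = "NC") {
  test <- match.arg(test)
  prefix <- test_prefix(test)
  df <- norm_cohort[as.character(norm_cohort$group) == group, , drop = FALSE]
  cols <- c(paste0(prefix, "_bl"), paste0(prefix, "_fu"), "age", "iq")
  df <- df[stats::complete.cases(df[, cols]), , drop = FALSE]
  if (nrow(df) <= 4) {
    stop("norm group has too few complete cases (", nrow(df), ")", call. = FALSE)
  }
  m <- mean(df[[cols[1]]])
  s <- stats::sd(df[[cols[1]]])
  if (s == 0) stop("zero baseline SD in norm group", call. = FALSE)
  anchors <- list(mean = m, sd = s)
  bl_z <- zscore(df[[cols[1]]], test, anchors)
  fu_z <- zscore(df[[cols[2]]], test, anchors)
  fit <- stats::lm(fu_z ~ bl_z + age + iq,
                   data = data.frame(fu_z, bl_z, age = df$age, iq = df$iq))
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient norm regression for ", test, call. = FALSE)
  }
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "baseline_z", "age", "iq")
  norm_model(test, m, s, cf, nrow(df))
}

#' Regression-based residual change scores
#'
#' Standardizes both timepoints of every participant against the norm
#' anchors, predicts the follow-up z from the norm-group regression
#' (baseline z, age, IQ), and returns the residual
#' `observed - predicted`: positive residuals mean better-than-expected
#' follow-up performance. Participants with a missing covariate or score
#' are excluded with a message. By construction the norm-group residuals
#' average to zero.
#'
#' @param cohort Full cohort table (all groups).
#' @param norm A fitted `dynfc_norm_model` for `test`.
#' @param test Test label.
#' @return Data frame with columns `participant_id`, `group`,
#'   `baseline_z`, `followup_z`, `predicted`, `residual`.
#' @export
residual_scores <- function(cohort, norm, test = c("HVLT_IR", "TMTB")) {
  test <- match.arg(test)
  stopifnot(inherits(norm, "dynfc_norm_model"), norm$test == test)
  prefix <- test_prefix(test)
  cols <- c(paste0(prefix, "_bl"), paste0(prefix, "_fu"), "age", "iq")
  complete <- stats::complete.cases(cohort[, cols])
  if (any(!complete)) {
    message("excluding ", sum(!complete), " participant(s) with missing ",
            test, " data: ",
            paste(cohort$participant_id[!complete], collapse = ", "))
  }
  df <- cohort[complete, , drop = FALSE]
  bl_z <- zscore(df[[cols[1]]], test, norm)
  fu_z <- zscore(df[[cols[2]]], test, norm)
  cf <- norm$coef
  predicted <- cf[["intercept"]] + cf[["baseline_z"]] * bl_z +
    cf[["age"]] * df$age + cf[["iq"]] * df$iq
  data.frame(participant_id = df$participant_id, group = df$group,
             baseline_z = bl_z, followup_z = fu_z,
             predicted = predicted, residual = fu_z - predicted,
             row.names = NULL)
}

#' One-way between-groups ANOVA
#'
#' Standard between/within sums-of-squares decomposition with F on
#' (k - 1, n - k) degrees of freedom, as used for group comparisons of
#' residual change scores and head-motion summaries.
#'
#' @param values Numeric response vector.
#' @param group Factor (or coercible) of group membership.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.01).
#' @return A one-row [model_result()] data frame with term `"group"`.
#' @export
oneway_anova <- function(values, group, alpha = 0.01) {
  group <- factor(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(group[keep])
  counts <- table(group)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("group(s) with fewer than 2 values: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  k <- length(counts)
  n <- length(values)
  if (stats::sd(values) == 0) {       # constant response: no variance to split
    return(model_result("group", f = 0, df_num = k - 1, df_den = n - k,
                        p = 1, alpha = alpha))
  }
  fit <- stats::anova(stats::lm(values ~ group))
  model_result("group", f = fit$`F value`[1],
               df_num = fit$Df[1], df_den = fit$Df[2],
               p = fit$`Pr(>F)`[1], alpha = alpha)
}

#' Pooled-SD standardized effect size
#'
#' Mean difference between two groups divided by the pooled standard
#' deviation `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`
#' (Cohen's d with pooled SD). Antisymmetric under swapping the groups.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return Scalar effect size.
#' @export
pooled_effect_size <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / pooled
}

#' Round half away from zero
#'
#' Reporting convention for effect-size tables; full precision is retained
#' internally and rounding is applied only at output time.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Group summary of residual change scores
#'
#' Builds the cognitive-performance summary for one test: per-group mean
#' and SD of the residual change scores, pooled-SD effect sizes of the
#' chemotherapy group against each comparison group, and the one-way ANOVA
#' p-value.
#'
#' @inheritParams residual_scores
#' @param alpha Passed to [oneway_anova()].
#' @return List with elements `summary` (per-group n/mean/sd), `effect_sizes`
#'   (BCC_PLUS vs BCC_MINUS and vs NC), and `anova` (a [model_result()] row).
#' @export
cognition_summary <- function(cohort, norm, test = c("HVLT_IR", "TMTB"),
                              alpha = 0.01) {
  test <- match.arg(test)
  rs <- residual_scores(cohort, norm, test)
  agg <- do.call(rbind, lapply(split(rs$residual, rs$group), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  agg$group <- rownames(agg)
  rownames(agg) <- NULL
  es <- vapply(c("BCC_MINUS", "NC"), function(g) {
    a <- agg[agg$group == "BCC_PLUS", ]
    b <- agg[agg$group == g, ]
    pooled_effect_size(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
  }, numeric(1))
  list(summary = agg[, c("group", "n", "mean", "sd")],
       effect_sizes = es,
       anova = oneway_anova(rs$residual, rs$group, alpha = alpha))
}
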