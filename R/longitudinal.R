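#' Delta scores of a connectivity measure
#'
#' Follow-up minus baseline, one row per participant. Connectivity change
#' is summarized by simple differences (not regression-corrected change),
#' since linearity of change over time is not assumed for imaging
#' measures.
#'
#' @param cohort Cohort table with the measure's per-timepoint columns.
#' @param measure `"DMN_dFC"`, `"FPN_dFC"` or `"WB_dFC"`.
#' @return Data frame with columns `participant_id`, `measure`, `delta`.
#'   Participants missing either timepoint are excluded with a message.
#' @export
delta_scores <- function(cohort, measure = c("DMN_dFC", "FPN_dFC", "WB_dFC")) {
  measure <- match.arg(measure)
  cols <- measure_columns(measure)
  keep <- stats::complete.cases(cohort[, cols])
  if (any(!keep)) {
    message("excluding ", sum(!keep), " participant(s) with missing ",
            measure, ": ", paste(cohort$participant_id[!keep], collapse = ", "))
  }
  df <- cohort[keep, , drop = FALSE]
  data.frame(participant_id = df$participant_id, measure = measure,
             delta = df[[cols[2]]] - df[[cols[1]]], row.names = NULL)
}

measure_columns <- function(measure) {
  switch(measure,
         DMN_dFC = c("dmn_bl", "dmn_fu"),
         FPN_dFC = c("fpn_bl", "fpn_fu"),
         WB_dFC = c("wb_bl", "wb_fu"),
         stop("unknown measure: ", measure, call. = FALSE))
}

# ---- Type-III repeated-measures machinery --------------------------------
#
# Two timepoints allow an exact decomposition: between-subject terms are
# tested on per-subject means across time, within-subject terms (those
# involving time) on per-subject differences. Each block is an ordinary
# linear model; Type-III-style F statistics come from full-vs-reduced
# comparisons with sum-to-zero group coding and grand-mean-centered
# continuous predictors, matching the full-factorial convention for
# unbalanced groups.

build_blocks <- function(group, delta = NULL, covariates = NULL) {
  n <- length(group)
  blocks <- list(`(Intercept)` = matrix(1, n, 1))
  g <- stats::model.matrix(~group, contrasts.arg = list(group = "contr.sum"))
  blocks$group <- g[, -1, drop = FALSE]
  if (!is.null(delta)) {
    delta_c <- delta - mean(delta)
    blocks$dfc_change <- matrix(delta_c, n, 1)
    blocks$`group:dfc_change` <- blocks$group * delta_c
  }
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      blocks[[nm]] <- matrix(covariates[[nm]] - mean(covariates[[nm]]), n, 1)
    }
  }
  blocks
}

type3_block <- function(y, blocks, test_terms, term_names, alpha) {
  X <- do.call(cbind, blocks)
  n <- length(y)
  p <- ncol(X)
  qr_full <- qr(X)
  if (qr_full$rank < p) {
    for (term in names(blocks)) {
      rest <- do.call(cbind, blocks[setdiff(names(blocks), term)])
      if (qr(rest)$rank == qr_full$rank) {
        stop("rank-deficient design: term ", term,
             " is aliased (e.g., constant predictor)", call. = FALSE)
      }
    }
    stop("rank-deficient design matrix", call. = FALSE)
  }
  rss_full <- sum(qr.resid(qr_full, y)^2)
  df_res <- n - p
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  rows <- lapply(seq_along(test_terms), function(i) {
    term <- test_terms[i]
    reduced <- do.call(cbind, blocks[setdiff(names(blocks), term)])
    rss_red <- sum(qr.resid(qr(reduced), y)^2)
    q <- ncol(blocks[[term]])
    # degenerate response (e.g. follow-up identical to baseline for all):
    # zero residual variance with no term contribution means F = 0
    if (rss_full <= .Machine$double.eps * max(1, rss_red)) {
      f <- if (rss_red - rss_full <= .Machine$double.eps) 0 else Inf
    } else {
      f <- max(((rss_red - rss_full) / q) / (rss_full / df_res), 0)
    }
    model_result(term_names[i], f = f, df_num = q, df_den = df_res,
                 p = stats::pf(f, q, df_res, lower.tail = FALSE),
                 alpha = alpha)
  })
  do.call(rbind, rows)
}

#' Repeated-measures ANOVA/ANCOVA on two-timepoint data
#'
#' Core fitting routine for the two-timepoint repeated-measures designs:
#' a between-subjects factor `group` (sum-to-zero coded), an optional
#' continuous per-subject predictor `delta` (a connectivity change score,
#' grand-mean-centered), their interaction, and optional continuous
#' covariates. Between-subject effects are tested on per-subject means of
#' the two timepoints; effects involving time on per-subject differences
#' (follow-up minus baseline), where the intercept tests the time main
#' effect. Covariates enter both blocks (nuisance in the within block), so
#' both error strata share the same residual degrees of freedom.
#'
#' @param y_bl,y_fu Numeric response at baseline and follow-up.
#' @param group Factor of group membership.
#' @param delta Optional numeric per-subject continuous predictor.
#' @param covariates Optional data.frame of continuous covariates
#'   (e.g. `age`, `iq`).
#' @param alpha Significance threshold (default 0.01, chosen to limit
#'   type-I risk across multiple terms without further correction).
#' @return A [model_result()] data.frame with one row per tested term:
#'   `group`, then (if `delta` given) `dfc_change` and `group:dfc_change`,
#'   covariate main effects, then `time`, `group:time` and (if `delta`)
#'   `dfc_change:time`, `group:dfc_change:time`.
#' @export
rm_ancova_fit <- function(y_bl, y_fu, group, delta = NULL, covariates = NULL,
                          alpha = 0.01) {
  group <- droplevels(factor(group))
  n <- length(y_bl)
  stopifnot(length(y_fu) == n, length(group) == n)
  if (!is.null(delta)) stopifnot(length(delta) == n)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  blocks <- build_blocks(group, delta, covariates)
  between_terms <- setdiff(names(blocks), "(Intercept)")
  within_source <- c("(Intercept)", "group",
                     if (!is.null(delta)) c("dfc_change", "group:dfc_change"))
  within_names <- c("time", "group:time",
                    if (!is.null(delta)) c("dfc_change:time",
                                           "group:dfc_change:time"))
  m <- (y_bl + y_fu) / 2
  d <- y_fu - y_bl
  between <- type3_block(m, blocks, between_terms, between_terms, alpha)
  within <- type3_block(d, blocks, within_source, within_names, alpha)
  rbind(between, within)
}

#' Group-by-time repeated-measures ANOVA on a dFC measure
#'
#' Tests group differences, change over time, and their interaction for
#' one network dFC summary across the two timepoints.
#'
#' @param cohort Cohort table with per-timepoint dFC columns.
#' @param measure `"DMN_dFC"`, `"FPN_dFC"` or `"WB_dFC"`.
#' @param alpha Significance threshold.
#' @return A [model_result()] data.frame with terms `group`, `time`,
#'   `group:time`.
#' @export
mixed_anova_dfc <- function(cohort, measure = c("DMN_dFC", "FPN_dFC", "WB_dFC"),
                            alpha = 0.01) {
  measure <- match.arg(measure)
  cols <- measure_columns(measure)
  keep <- stats::complete.cases(cohort[, cols])
  df <- cohort[keep, , drop = FALSE]
  counts <- table(droplevels(factor(df$group)))
  if (any(counts < 3)) {
    stop("group(s) with fewer than 3 complete cases: ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  }
  rm_ancova_fit(df[[cols[1]]], df[[cols[2]]], df$group, alpha = alpha)
}

#' Specification of the cognition-connectivity ANCOVA
#'
#' Pairs a cognitive outcome with its hypothesized network change score:
#' memory (HVLT-R immediate recall) with default-mode network dFC change,
#' executive function (TMT-B) with frontoparietal dFC change. The pairing
#' is a default, not a constraint.
#'
#' @param dependent `"HVLT_IR"` or `"TMTB"`.
#' @param predictor Connectivity change measure; defaults to the
#'   hypothesis-matched network (`DMN_dFC` for memory, `FPN_dFC` for
#'   executive function).
#' @param covariates Covariate column names (default age and premorbid IQ).
#' @param alpha Significance threshold (default 0.01).
#' @return A `dynfc_ancova_spec` object.
#' @export
ancova_spec <- function(dependent = c("HVLT_IR", "TMTB"), predictor = NULL,
                        covariates = c("age", "iq"), alpha = 0.01) {
  dependent <- match.arg(dependent)
  if (is.null(predictor)) {
    predictor <- if (dependent == "HVLT_IR") "DMN_dFC" else "FPN_dFC"
  }
  predictor <- match.arg(predictor, c("DMN_dFC", "FPN_dFC", "WB_dFC"))
  stopifnot(alpha > 0, alpha < 1)
  structure(list(dependent = dependent, predictor = predictor,
                 covariates = covariates, alpha = alpha),
            class = "dynfc_ancova_spec")
}

#' Three-way repeated-measures ANCOVA linking cognition to dFC change
#'
#' Full-factorial repeated-measures analysis of covariance on one
#' cognitive outcome: between-subjects factor group, within-subjects
#' factor time (baseline/follow-up), the continuous connectivity change
#' score (delta of the paired network dFC), all their interactions, and
#' age/IQ covariates. Scores are standardized against the normative
#' group's baseline before fitting (F statistics are invariant to this
#' affine step; the slope table is reported on the z scale so that higher
#' always means better performance). Complete-case analysis throughout.
#'
#' @param cohort Cohort table with cognitive scores, covariates and
#'   per-timepoint dFC columns.
#' @param spec An [ancova_spec()].
#' @param norm Optional `dynfc_norm_model` for the dependent test; when
#'   `NULL`, z-anchors are computed from the cohort's NC baseline.
#' @return List with `results` (a [model_result()] data.frame),
#'   `slopes` (per-group OLS slope of the cognitive change score on the
#'   centered dFC change, for slope-inhomogeneity displays), and `n`
#'   (complete cases used).
#' @export
rm_ancova <- function(cohort, spec = ancova_spec(), norm = NULL) {
  stopifnot(inherits(spec, "dynfc_ancova_spec"))
  prefix <- test_prefix(spec$dependent)
  dfc_cols <- measure_columns(spec$predictor)
  cols <- c(paste0(prefix, "_bl"), paste0(prefix, "_fu"), dfc_cols,
            spec$covariates)
  keep <- stats::complete.cases(cohort[, cols])
  if (any(!keep)) {
    message("excluding ", sum(!keep), " incomplete participant(s): ",
            paste(cohort$participant_id[!keep], collapse = ", "))
  }
  df <- cohort[keep, , drop = FALSE]
  if (is.null(norm)) {
    nc <- df[as.character(df$group) == "NC", paste0(prefix, "_bl")]
    if (length(nc) < 2 || stats::sd(nc) == 0) {
      stop("cannot derive z-anchors from NC baseline", call. = FALSE)
    }
    norm <- list(mean = mean(nc), sd = stats::sd(nc))
  }
  y_bl <- zscore(df[[cols[1]]], spec$dependent, norm)
  y_fu <- zscore(df[[cols[2]]], spec$dependent, norm)
  delta <- df[[dfc_cols[2]]] - df[[dfc_cols[1]]]
  covs <- df[, spec$covariates, drop = FALSE]
  results <- rm_ancova_fit(y_bl, y_fu, df$group, delta = delta,
                           covariates = covs, alpha = spec$alpha)
  delta_c <- delta - mean(delta)
  d <- y_fu - y_bl
  slopes <- vapply(split(seq_along(d), droplevels(factor(df$group))),
                   function(idx) {
                     unname(stats::coef(stats::lm(d[idx] ~ delta_c[idx]))[2])
                   }, numeric(1))
  list(results = results, slopes = slopes, n = nrow(df))
}
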