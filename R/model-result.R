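#' Model-result rows
#'
#' Uniform container for ANOVA/ANCOVA effects: term name, F statistic,
#' numerator/denominator degrees of freedom, two-sided p-value and a
#' significance flag at the configured alpha. The flag uses a strict
#' inequality, so a boundary p exactly equal to alpha is not significant.
#'
#' @param term Effect name(s).
#' @param f F statistic(s), >= 0.
#' @param df_num,df_den Degrees of freedom (positive integers).
#' @param p Two-sided p-value(s) in \[0, 1\].
#' @param alpha Significance threshold in (0, 1).
#' @return A data.frame with columns `term`, `f_value`, `df_num`, `df_den`,
#'   `p_value`, `significant`.
#' @export
model_result <- function(term, f, df_num, df_den, p, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(f < 0) || any(p < 0 | p > 1)) {
    stop("invalid F or p value", call. = FALSE)
  }
  df_num <- as.integer(df_num)
  df_den <- as.integer(df_den)
  if (any(df_num < 1) || any(df_den < 1)) {
    stop("degrees of freedom must be positive integers", call. = FALSE)
  }
  data.frame(term = term, f_value = f, df_num = df_num, df_den = df_den,
             p_value = p, significant = p < alpha, row.names = NULL)
}
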