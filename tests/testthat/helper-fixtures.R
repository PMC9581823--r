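# Shared fixtures and independent oracles. Oracles are deliberately naive
# (two-pass formulas, exhaustive enumeration) and never call the code paths
# they check.

toy_region_table <- function(n = 4, dmn = 1:2, fpn = integer(0),
                             subcortical = integer(0)) {
  network <- rep("OTHER_CORTICAL", n)
  network[dmn] <- "DMN"
  network[fpn] <- "FPN"
  network[subcortical] <- "SUBCORTICAL"
  data.frame(region_id = seq_len(n), name = paste0("r", seq_len(n)),
             cortical = network != "SUBCORTICAL", network = network,
             stringsAsFactors = FALSE)
}

toy_ts <- function(n_regions = 3, n_volumes = 40, seed = 1, tr = 2.1) {
  set.seed(seed)
  m <- matrix(rnorm(n_regions * n_volumes), n_regions, n_volumes)
  rownames(m) <- paste0("r", seq_len(n_regions))
  timeseries_matrix(m, tr)
}

# textbook two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exhaustive enumeration of fully contained windows starting on the step grid
windows_oracle <- function(T, L, S) {
  starts <- integer(0)
  for (s in seq_len(T)) {
    if ((s - 1) %% S == 0 && s + L - 1 <= T) starts <- c(starts, s)
  }
  starts
}

# mean over explicitly enumerated member-to-rest pairs
network_mean_oracle <- function(dfc, members) {
  rest <- setdiff(seq_len(nrow(dfc)), members)
  vals <- c()
  for (i in members) for (j in rest) vals <- c(vals, dfc[i, j])
  mean(vals[is.finite(vals)])
}

# one-way ANOVA by explicit sums of squares
oneway_oracle <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, df1 = k - 1, df2 = n - k,
       p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# analytic two-timepoint cohort (no time series), for model-level tests:
# group-specific slopes of follow-up z on a per-subject continuous delta
analytic_cohort <- function(n_per_group = c(34, 32, 35),
                            slopes = c(0, 0, 0),
                            time_shift = 0, noise_sd = 1,
                            beta_age = 0, beta_iq = 0, seed = 1) {
  set.seed(seed)
  groups <- factor(rep(c("BCC_PLUS", "BCC_MINUS", "NC"), times = n_per_group),
                   levels = c("BCC_PLUS", "BCC_MINUS", "NC"))
  n <- length(groups)
  age <- rnorm(n, 50, 9)
  iq <- rnorm(n, 104, 13)
  delta <- rnorm(n)
  y_bl <- rnorm(n)
  y_fu <- y_bl * 0 + time_shift + slopes[as.integer(groups)] * delta +
    beta_age * (age - mean(age)) + beta_iq * (iq - mean(iq)) +
    rnorm(n, 0, noise_sd)
  data.frame(group = groups, age = age, iq = iq, delta = delta,
             y_bl = y_bl, y_fu = y_fu)
}

exact_binomial_bounds <- function(n, p, conf = 0.95) {
  lo <- qbinom((1 - conf) / 2, n, p)
  hi <- qbinom(1 - (1 - conf) / 2, n, p)
  c(lo, hi)
}
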