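#' Synthetic-cohort simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults mirror
#' the study design the pipeline targets: three groups of 34/32/35
#' participants (chemotherapy-treated and untreated breast cancer, and
#' no-cancer controls), two timepoints, 90-region parcellation, 180
#' volumes at TR = 2.1 s, age ~ Normal(50, 9) years and premorbid
#' IQ ~ Normal(104, 13).
#'
#' BOLD-like signals are built from AR(1) noise (coefficient
#' `ar_coefficient`) with a per-region coupling to one of three latent
#' network signals (DMN, FPN, other) whose strength oscillates
#' sinusoidally: `w_r(t) = w0 + a sin(2 pi t / P_r + phi_r)` with period
#' `P_r` and phase `phi_r` drawn per region. The modulation depth `a` is
#' the dynamic ground truth: `a = 0` is truly static coupling, larger `a`
#' means deeper genuine connectivity dynamics.
#'
#' Cognitive follow-up scores are linearly coupled to the *true* change in
#' modulation depth with group-specific slopes, so the measured dFC delta
#' acts as a noisy proxy; the default slopes reverse sign for the
#' untreated-patient group, emulating the slope-inhomogeneity pattern the
#' pipeline is designed to detect. TMT-B is generated on the seconds scale
#' (higher = worse) so the standardization sign-flip path is exercised.
#'
#' @param n_per_group Named integer vector of group sizes
#'   (`BCC_PLUS`, `BCC_MINUS`, `NC`).
#' @param n_regions Number of regions (default 90; taken from the head of
#'   `regions`).
#' @param n_volumes Volumes per scan (default 180).
#' @param tr_seconds Repetition time (default 2.1 s).
#' @param ar_coefficient AR(1) coefficient of latent and noise signals
#'   (default 0.3).
#' @param base_coupling Baseline coupling w0 in \[0, 1) (default 0.55).
#' @param latent_correlation Shared-variance fraction of a global
#'   component common to the three latent network signals, in \[0, 1\]
#'   (default 0.8). A substantial shared component emulates the global
#'   BOLD signal (no global-signal regression is assumed) and puts mean
#'   between-region correlations near 0.25-0.3, the regime typical of
#'   parcellated resting-state data; it also makes between-network
#'   (member-to-rest) connections sensitive to coupling modulation, as
#'   they are in real data.
#' @param modulation_depth Either a scalar depth used for every
#'   group x timepoint, or a 3 x 2 matrix (rows `BCC_PLUS`, `BCC_MINUS`,
#'   `NC`; columns baseline, follow-up). Default 0.2. Must satisfy
#'   `w0 + a <= 1`.
#' @param modulation_depth_sd Between-participant SD of the true
#'   modulation depth around its group x timepoint value (default 0.05);
#'   realized depths are truncated into the coupling headroom
#'   `[0, 1 - w0]`. This individual variability is what makes within-group
#'   dFC-cognition slopes identifiable.
#' @param modulation_period_volumes Range the per-region modulation period
#'   is drawn from (default 40–80 volumes).
#' @param cognitive List of the cognitive ground-truth model:
#'   `baseline_mean` (per-group baseline z means), `intercept` (per-group
#'   follow-up z intercepts), `slope` (per-group slopes on the true
#'   modulation-depth change), `beta_age`, `beta_iq` (slopes on centered
#'   age/IQ), `noise_sd` (residual SD of follow-up z), `baseline_sd`.
#' @param hvlt_norm,tmtb_norm Raw-scale anchors `c(mean, sd)` used to map
#'   z-scores to raw words recalled / seconds.
#' @param age_mean,age_sd,iq_mean,iq_sd Demographic distributions.
#' @param motion_mean,motion_sd Head-motion summary distribution (mm).
#' @param regions Region table (default the bundled 90-region fixture).
#' @param seed Master seed; all randomness flows from it through
#'   documented per-participant sub-seeds.
#' @return A `dynfc_sim_config` object.
#' @export
sim_config <- function(n_per_group = c(BCC_PLUS = 34L, BCC_MINUS = 32L, NC = 35L),
                       n_regions = 90L,
                       n_volumes = 180L,
                       tr_seconds = 2.1,
                       ar_coefficient = 0.3,
                       base_coupling = 0.55,
                       latent_correlation = 0.8,
                       modulation_depth = 0.2,
                       modulation_depth_sd = 0.05,
                       modulation_period_volumes = c(40, 80),
                       cognitive = list(),
                       hvlt_norm = c(mean = 25, sd = 5),
                       tmtb_norm = c(mean = 75, sd = 25),
                       age_mean = 50, age_sd = 9,
                       iq_mean = 104, iq_sd = 13,
                       motion_mean = 0.25, motion_sd = 0.15,
                       regions = NULL,
                       seed = 1L) {
  if (is.null(regions)) regions <- default_region_table()
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2, n_regions <= nrow(regions))
  regions <- regions[seq_len(n_regions), , drop = FALSE]
  if (is.null(names(n_per_group))) names(n_per_group) <- GROUP_LABELS
  stopifnot(all(GROUP_LABELS %in% names(n_per_group)), all(n_per_group >= 2))
  depth <- modulation_depth
  if (length(depth) == 1) {
    depth <- matrix(depth, 3, 2, dimnames = list(GROUP_LABELS, c("bl", "fu")))
  } else {
    depth <- as.matrix(depth)
    stopifnot(identical(dim(depth), c(3L, 2L)))
    if (is.null(rownames(depth))) rownames(depth) <- GROUP_LABELS
    colnames(depth) <- c("bl", "fu")
  }
  if (base_coupling < 0 || base_coupling >= 1) {
    stop("base coupling must lie in [0, 1)", call. = FALSE)
  }
  if (latent_correlation < 0 || latent_correlation > 1) {
    stop("latent correlation must lie in [0, 1]", call. = FALSE)
  }
  if (any(depth < 0) || any(base_coupling + depth > 1)) {
    stop("coupling headroom violated: need 0 <= a and w0 + a <= 1",
         call. = FALSE)
  }
  cog_defaults <- list(
    baseline_mean = c(BCC_PLUS = 0, BCC_MINUS = 0, NC = 0),
    intercept = c(BCC_PLUS = 0, BCC_MINUS = 0, NC = 0),
    slope = c(BCC_PLUS = -0.4, BCC_MINUS = 0.4, NC = -0.4),
    beta_age = -0.03, beta_iq = 0.02,
    noise_sd = 1, baseline_sd = 1)
  cognitive <- utils::modifyList(cog_defaults, cognitive)
  stopifnot(cognitive$noise_sd >= 0, cognitive$baseline_sd >= 0,
            modulation_depth_sd >= 0, age_sd > 0, iq_sd > 0)
  structure(list(n_per_group = n_per_group[GROUP_LABELS],
                 n_regions = n_regions, n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, ar_coefficient = ar_coefficient,
                 base_coupling = base_coupling,
                 latent_correlation = latent_correlation,
                 modulation_depth = depth,
                 modulation_depth_sd = modulation_depth_sd,
                 modulation_period_volumes = modulation_period_volumes,
                 cognitive = cognitive,
                 hvlt_norm = hvlt_norm, tmtb_norm = tmtb_norm,
                 age_mean = age_mean, age_sd = age_sd,
                 iq_mean = iq_mean, iq_sd = iq_sd,
                 motion_mean = motion_mean, motion_sd = motion_sd,
                 regions = regions, seed = as.integer(seed)),
            class = "dynfc_sim_config")
}

ar1 <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate one BOLD-like scan
#'
#' Generates a regions x volumes matrix: each region tracks the latent
#' AR(1) signal of its network (DMN, FPN, or a shared "other" signal for
#' remaining cortical and subcortical regions) with sinusoidally modulated
#' coupling depth `a`, plus independent AR(1) noise scaled so the
#' per-volume variance is 1 before final per-region standardization
#' (mean 0, SD 1).
#'
#' @param config A [sim_config()].
#' @param a Modulation depth for this scan (defaults to the config's
#'   `BCC_PLUS` baseline entry).
#' @param seed Scan-level seed (bit-identical regeneration).
#' @return A `dynfc_ts`.
#' @export
simulate_timeseries <- function(config, a = NULL, seed = 1L) {
  stopifnot(inherits(config, "dynfc_sim_config"))
  if (is.null(a)) a <- config$modulation_depth["BCC_PLUS", "bl"]
  w0 <- config$base_coupling
  if (a < 0 || w0 + a > 1) {
    stop("coupling headroom violated: need 0 <= a and w0 + a <= 1",
         call. = FALSE)
  }
  regions <- config$regions
  n <- config$n_regions
  T_ <- config$n_volumes
  phi <- config$ar_coefficient
  set.seed(as.integer(seed))
  latent_of <- ifelse(regions$network == "DMN", "DMN",
                      ifelse(regions$network == "FPN", "FPN", "OTHER"))
  lc <- config$latent_correlation
  global <- ar1(T_, phi)
  latents <- lapply(c(DMN = 1, FPN = 2, OTHER = 3), function(...) {
    sqrt(lc) * global + sqrt(1 - lc) * ar1(T_, phi)
  })
  periods <- stats::runif(n, config$modulation_period_volumes[1],
                          config$modulation_period_volumes[2])
  phases <- stats::runif(n, 0, 2 * pi)
  tau <- seq_len(T_)
  out <- matrix(0, n, T_)
  for (r in seq_len(n)) {
    w <- w0 + a * sin(2 * pi * tau / periods[r] + phases[r])
    eps <- ar1(T_, phi)
    x <- w * latents[[latent_of[r]]] + sqrt(pmax(1 - w^2, 0)) * eps
    out[r, ] <- (x - mean(x)) / stats::sd(x)
  }
  rownames(out) <- regions$name
  timeseries_matrix(out, config$tr_seconds, regions$region_id)
}

participant_seed <- function(master, index, timepoint) {
  # counter scheme keeping every derived seed inside 32-bit integer range
  (as.integer(master) + 7919L * as.integer(index) + as.integer(timepoint)) %%
    .Machine$integer.max
}

#' Simulate a full three-group, two-timepoint cohort
#'
#' Draws demographics, per-timepoint modulation depths from the config,
#' cognitive scores linearly coupled to the true modulation change with
#' group-specific slopes, and (optionally) the BOLD-like time series
#' themselves. Without time series, the per-timepoint dFC columns are
#' filled with a noisy proxy of the true modulation depth
#' (`a + Normal(0, 0.02)`, truncated at 0) so cohort-level statistics can
#' be exercised cheaply; with time series, dFC columns are left `NA` to be
#' filled by [compute_cohort_dfc()].
#'
#' @param config A [sim_config()].
#' @param timeseries One of `"none"` (proxy dFC columns), `"memory"`
#'   (return `dynfc_ts` objects in-memory), `"files"` (write TSVs under
#'   `out_dir` and record paths in the manifest).
#' @param out_dir Output directory, required for `timeseries = "files"`;
#'   also receives `cohort.csv` and `truth.csv`.
#' @return List with `cohort` (validated cohort table), `truth`
#'   (per-participant true modulation depths and slopes), and `timeseries`
#'   (named list `"<id>_bl"` / `"<id>_fu"`, or `NULL`).
#' @export
simulate_cohort <- function(config, timeseries = c("none", "memory", "files"),
                            out_dir = NULL) {
  stopifnot(inherits(config, "dynfc_sim_config"))
  timeseries <- match.arg(timeseries)
  if (timeseries == "files" && is.null(out_dir)) {
    stop("out_dir required when writing time-series files", call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  cog <- config$cognitive
  groups <- rep(GROUP_LABELS, times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("P%03d", seq_len(n))
  set.seed(config$seed)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  iq <- stats::rnorm(n, config$iq_mean, config$iq_sd)
  age_c <- age - mean(age)
  iq_c <- iq - mean(iq)
  headroom <- 1 - config$base_coupling
  jitter <- function(a) {
    pmin(pmax(a + stats::rnorm(n, 0, config$modulation_depth_sd), 0), headroom)
  }
  a_bl <- jitter(config$modulation_depth[groups, "bl"])
  a_fu <- jitter(config$modulation_depth[groups, "fu"])
  delta_a <- a_fu - a_bl

  draw_test <- function(anchors, flip) {
    bl_z <- stats::rnorm(n, cog$baseline_mean[groups], cog$baseline_sd)
    fu_z <- cog$intercept[groups] + cog$slope[groups] * delta_a +
      cog$beta_age * age_c + cog$beta_iq * iq_c +
      stats::rnorm(n, 0, cog$noise_sd)
    sgn <- if (flip) -1 else 1
    list(bl = anchors[["mean"]] + sgn * anchors[["sd"]] * bl_z,
         fu = anchors[["mean"]] + sgn * anchors[["sd"]] * fu_z)
  }
  hvlt <- draw_test(config$hvlt_norm, flip = FALSE)
  tmtb <- draw_test(config$tmtb_norm, flip = TRUE)
  motion <- function() pmax(stats::rnorm(n, config$motion_mean,
                                         config$motion_sd), 0.01)
  cohort <- data.frame(participant_id = ids, group = groups,
                       age = age, iq = iq,
                       hvlt_bl = hvlt$bl, hvlt_fu = hvlt$fu,
                       tmtb_bl = tmtb$bl, tmtb_fu = tmtb$fu,
                       motion_bl = motion(), motion_fu = motion())
  truth <- data.frame(participant_id = ids, group = groups,
                      a_bl = a_bl, a_fu = a_fu, delta_a = delta_a,
                      slope = unname(cog$slope[groups]), row.names = NULL)
  ts_list <- NULL
  if (timeseries == "none") {
    proxy <- function(a) pmax(a + stats::rnorm(n, 0, 0.02), 0)
    cohort$dmn_bl <- proxy(a_bl); cohort$dmn_fu <- proxy(a_fu)
    cohort$fpn_bl <- proxy(a_bl); cohort$fpn_fu <- proxy(a_fu)
    cohort$wb_bl <- proxy(a_bl); cohort$wb_fu <- proxy(a_fu)
  } else {
    ts_list <- list()
    for (i in seq_len(n)) {
      for (tp in 1:2) {
        a <- if (tp == 1) a_bl[i] else a_fu[i]
        ts <- simulate_timeseries(config, a = a,
                                  seed = participant_seed(config$seed, i, tp))
        key <- paste0(ids[i], if (tp == 1) "_bl" else "_fu")
        if (timeseries == "files") {
          path <- file.path(out_dir, paste0(key, ".tsv"))
          write_timeseries(ts, path)
          ts_list[[key]] <- path
        } else {
          ts_list[[key]] <- ts
        }
      }
    }
    if (timeseries == "files") {
      cohort$ts_bl_path <- unlist(ts_list[paste0(ids, "_bl")])
      cohort$ts_fu_path <- unlist(ts_list[paste0(ids, "_fu")])
    }
    for (col in DFC_COLUMNS) cohort[[col]] <- NA_real_
  }
  cohort <- validate_cohort(cohort)
  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(cohort = cohort, truth = truth, timeseries = ts_list)
}

#' Fill per-timepoint dFC summaries for a simulated or loaded cohort
#'
#' Runs the sliding-window CoV pipeline on every participant-timepoint
#' series and writes `dmn_*`, `fpn_*`, `wb_*` columns into the cohort
#' table.
#'
#' @param cohort Cohort table.
#' @param ts_list Named list `"<id>_bl"` / `"<id>_fu"` of `dynfc_ts`
#'   objects (as from [simulate_cohort()] with `timeseries = "memory"`).
#' @param regions Region table matching the series.
#' @param spec A [window_spec()].
#' @param mean_floor Passed to [cov_dfc()].
#' @param tr_seconds Repetition time attached when entries of `ts_list`
#'   are file paths rather than `dynfc_ts` objects.
#' @return The cohort table with dFC columns filled.
#' @export
compute_cohort_dfc <- function(cohort, ts_list, regions,
                               spec = window_spec(), mean_floor = 1e-6,
                               tr_seconds = 2.1) {
  for (i in seq_len(nrow(cohort))) {
    for (tp in c("bl", "fu")) {
      key <- paste0(cohort$participant_id[i], "_", tp)
      ts <- ts_list[[key]]
      if (is.null(ts)) next
      if (is.character(ts)) ts <- read_timeseries(ts, regions, tr_seconds)
      s <- dfc_summaries(ts, regions, spec, mean_floor)
      cohort[i, paste0(c("dmn_", "fpn_", "wb_"), tp)] <-
        s[c("DMN_dFC", "FPN_dFC", "WB_dFC")]
    }
  }
  cohort
}
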