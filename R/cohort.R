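#' Cohort manifests
#'
#' A cohort table holds one row per participant: id, group
#' (`BCC_PLUS` = breast cancer treated with chemotherapy, `BCC_MINUS` =
#' breast cancer without chemotherapy, `NC` = no-cancer control), age at
#' baseline in years, premorbid IQ (NART estimate), raw neuropsychological
#' scores at both timepoints (HVLT-R immediate recall in words, higher is
#' better; TMT-B completion time in seconds, higher is worse), optional
#' mean head displacement per timepoint (mm), optional network dFC
#' summaries per timepoint, and optional paths to the time-series files.
#'
#' Group labels are canonicalized case-insensitively: `"bcc+"`, `"BCC+"`
#' and `"bcc_plus"` all map to `BCC_PLUS`; all other strings are
#' exact-match.
#'
#' @param path CSV manifest path with header columns
#'   `participant_id,group,age,iq,hvlt_bl,hvlt_fu,tmtb_bl,tmtb_fu` and any
#'   of the optional columns `motion_bl,motion_fu,ts_bl_path,ts_fu_path,
#'   dmn_bl,dmn_fu,fpn_bl,fpn_fu,wb_bl,wb_fu`.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

GROUP_LABELS <- c("BCC_PLUS", "BCC_MINUS", "NC")

#' Canonicalize group labels
#'
#' @param x Character vector of group labels in any supported spelling.
#' @return Character vector with entries in
#'   `c("BCC_PLUS", "BCC_MINUS", "NC")`.
#' @export
normalize_group <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[up %in% c("BCC+", "BCC_PLUS", "BCC PLUS", "BCC-PLUS")] <- "BCC_PLUS"
  up[up %in% c("BCC-", "BCC_MINUS", "BCC MINUS")] <- "BCC_MINUS"
  bad <- !(up %in% GROUP_LABELS)
  if (any(bad)) {
    stop("unknown group label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  up
}

DFC_COLUMNS <- c("dmn_bl", "dmn_fu", "fpn_bl", "fpn_fu", "wb_bl", "wb_fu")

#' Validate a cohort table
#'
#' @param df A data.frame of participants.
#' @return The validated data.frame with canonical group labels and a
#'   `group` factor ordered `BCC_PLUS, BCC_MINUS, NC`.
#' @export
validate_cohort <- function(df) {
  if (nrow(df) == 0) stop("no participants in cohort manifest", call. = FALSE)
  required <- c("participant_id", "group", "age", "iq",
                "hvlt_bl", "hvlt_fu", "tmtb_bl", "tmtb_fu")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort manifest missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup) > 0) {
    stop("duplicate participant id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df$group <- factor(normalize_group(df$group), levels = GROUP_LABELS)
  num_cols <- intersect(c("age", "iq", "hvlt_bl", "hvlt_fu", "tmtb_bl",
                          "tmtb_fu", "motion_bl", "motion_fu", DFC_COLUMNS),
                        names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (any(!is.na(df$age) & df$age < 0)) {
    stop("negative age for participant(s): ",
         paste(df$participant_id[!is.na(df$age) & df$age < 0], collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(DFC_COLUMNS, names(df))) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) {
      stop("negative dFC value in column ", col, " for participant(s): ",
           paste(df$participant_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' @rdname read_cohort
#' @param cohort A validated cohort table.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$group <- as.character(out$group)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group sample sizes
#' @param cohort A cohort table.
#' @return Named integer vector of counts per group.
#' @export
group_sizes <- function(cohort) {
  table(cohort$group)
}
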