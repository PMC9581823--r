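#' Region (parcellation) tables
#'
#' A region table describes the parcellation underlying all connectivity
#' computations: one row per region with a stable integer id, a label, a
#' cortical flag, and a resting-state network assignment. Only the default
#' mode network (`DMN`) and frontoparietal network (`FPN`) are first-class
#' labels; all other cortical regions carry `OTHER_CORTICAL` and subcortical
#' structures carry `SUBCORTICAL`.
#'
#' The bundled fixture (`default_region_table()`) covers the 90-region
#' cerebral subset of the AAL atlas (78 cortical + 12 subcortical) with
#' DMN/FPN memberships following the usual Yeo 7-network correspondence.
#' The assignment ships as an editable CSV so alternative mappings can be
#' swapped in without touching code.
#'
#' @param path Path to a CSV file with header columns
#'   `region_id,name,cortical,network`.
#' @return A `data.frame` with columns `region_id` (integer), `name`
#'   (character), `cortical` (logical) and `network` (character), validated
#'   against the invariants above.
#' @examples
#' regions <- default_region_table()
#' nrow(regions)            # 90
#' sum(regions$cortical)    # 78
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) {
    stop("region table file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(df)
}

#' @rdname read_region_table
#' @export
default_region_table <- function() {
  read_region_table(system.file("extdata", "aal90_yeo7.csv",
                                package = "dynfc", mustWork = TRUE))
}

NETWORK_LABELS <- c("DMN", "FPN", "OTHER_CORTICAL", "SUBCORTICAL")

#' Validate a region table
#'
#' Checks the invariants of the region-table contract: required columns,
#' unique contiguous ids, known network labels, and consistency between the
#' cortical flag and the network label (a subcortical region cannot belong
#' to a cortical network and vice versa). Errors name the offending row.
#'
#' @param df A data.frame as returned by [read_region_table()].
#' @return The validated data.frame, with columns coerced to their
#'   canonical types.
#' @export
validate_region_table <- function(df) {
  required <- c("region_id", "name", "cortical", "network")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("region table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("region table has no rows", call. = FALSE)
  df$region_id <- as.integer(df$region_id)
  df$cortical <- as.logical(df$cortical)
  if (anyNA(df$region_id)) stop("non-integer region_id", call. = FALSE)
  dup <- df$region_id[duplicated(df$region_id)]
  if (length(dup) > 0) {
    stop("duplicate region_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(sort(df$region_id), seq_len(nrow(df)))) {
    stop("region_ids must be contiguous 1..", nrow(df), call. = FALSE)
  }
  bad_net <- !(df$network %in% NETWORK_LABELS)
  if (any(bad_net)) {
    stop("unknown network label in row(s) ",
         paste(df$region_id[bad_net], collapse = ", "), ": ",
         paste(unique(df$network[bad_net]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$cortical)) stop("cortical flag must be TRUE/FALSE", call. = FALSE)
  mismatch <- (df$network == "SUBCORTICAL") == df$cortical
  if (any(mismatch)) {
    stop("cortical flag inconsistent with network label in row(s): ",
         paste(df$region_id[mismatch], collapse = ", "), call. = FALSE)
  }
  df[order(df$region_id), required, drop = FALSE]
}

#' @rdname read_region_table
#' @param regions A validated region table.
#' @export
write_region_table <- function(regions, path) {
  utils::write.csv(regions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Region ids belonging to a network
#'
#' @param regions A region table.
#' @param network One of `"DMN"`, `"FPN"`, `"OTHER_CORTICAL"`,
#'   `"SUBCORTICAL"`.
#' @return Integer vector of region ids.
#' @export
network_members <- function(regions, network) {
  network <- match.arg(network, NETWORK_LABELS)
  regions$region_id[regions$network == network]
}
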