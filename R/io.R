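# CSV readers/writers for the pipeline's tabular formats. All files are
# headered UTF-8 CSV; units ride in the column names (_s, _M, _mV).

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("'", path, "': missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read and write fragment-timecourse band tables
#'
#' CSV schema: `time_s, A, C, AB, BC, full_length` plus optional metadata
#' columns `trap_on`, `spacing_bp`, `condition` (constant per file).
#' Validation errors name the offending column or row.
#'
#' @param path CSV path.
#' @return `read_bands_csv`: a [fragment_timecourse()].
#' @export
read_bands_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("time_s", "A", "C", "AB", "BC", "full_length"), path)
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("'", path, "': time_s must be strictly increasing (row ",
         which(diff(df$time_s) <= 0)[1] + 1, ")")
  }
  frac <- as.matrix(df[, c("A", "C", "AB", "BC", "full_length")])
  if (any(frac < 0)) {
    bad <- which(rowSums(frac < 0) > 0)[1]
    stop("'", path, "': negative band fraction at row ", bad)
  }
  fragment_timecourse(df$time_s, df$A, df$C, df$AB, df$BC, df$full_length,
                      trap_on = if ("trap_on" %in% names(df))
                        as.logical(df$trap_on[1]) else FALSE,
                      site_spacing = if ("spacing_bp" %in% names(df))
                        df$spacing_bp[1] else NA_integer_,
                      condition = if ("condition" %in% names(df))
                        df$condition[1] else "unknown")
}

#' @rdname read_bands_csv
#' @param tc A [fragment_timecourse()].
#' @export
write_bands_csv <- function(tc, path) {
  stopifnot(inherits(tc, "fragment_timecourse"))
  out <- as.data.frame(tc)
  out$trap_on <- attr(tc, "trap_on")
  out$spacing_bp <- attr(tc, "site_spacing")
  out$condition <- attr(tc, "condition")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write stopped-flow kinetic traces
#'
#' CSV schema: `time_s, signal`, optional constant columns `P0_M`,
#' `condition`.
#'
#' @param path CSV path.
#' @return `read_trace_csv`: a [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("time_s", "signal"), path)
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("'", path, "': time_s must be strictly increasing")
  }
  kinetic_trace(df$time_s, df$signal,
                P0 = if ("P0_M" %in% names(df)) df$P0_M[1] else NA_real_,
                condition = if ("condition" %in% names(df))
                  df$condition[1] else "unknown")
}

#' @rdname read_trace_csv
#' @param trace A [kinetic_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  out <- as.data.frame(trace)
  out$P0_M <- attr(trace, "P0")
  out$condition <- attr(trace, "condition")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a typed table (titration, initial rates, ISE standards)
#'
#' @param path CSV path.
#' @param type One of `"titration"` (`conc_M`, `anisotropy`), `"rates"`
#'   (`conc_M`, `rate_Ms`), `"ise"` (`conc`, `mV`).
#' @return Validated data frame.
#' @export
read_table_csv <- function(path, type = c("titration", "rates", "ise")) {
  type <- match.arg(type)
  cols <- switch(type,
                 titration = c("conc_M", "anisotropy"),
                 rates = c("conc_M", "rate_Ms"),
                 ise = c("conc", "mV"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, cols, path)
  ccol <- cols[1]
  if (any(df[[ccol]] <= 0)) {
    stop("'", path, "': non-positive concentration at row ",
         which(df[[ccol]] <= 0)[1])
  }
  df
}

#' Consolidated run report
#'
#' Collects the outputs of completed pipeline stages into one
#' machine-readable structure: a transfer table (P_trans / P_assoc /
#' P_diss by condition and spacing), kinetic fit tables, and crowding
#' tables; stages not run are marked `"not run"`. Deterministic: two runs
#' with the same inputs and seed produce byte-identical JSON.
#'
#' @param transfer Named list of `transfer_result` / partition outputs, or
#'   NULL.
#' @param kinetics Named list of fit results, or NULL.
#' @param crowding Named list of crowding tables, or NULL.
#' @param seed The run's root RNG seed (recorded in the report).
#' @param path Optional path; if given, the JSON is written there.
#' @return The report list, invisibly if written.
#' @export
report <- function(transfer = NULL, kinetics = NULL, crowding = NULL,
                   seed = NA_integer_, path = NULL) {
  strip <- function(x) {
    if (is.list(x)) {
      x$fit <- NULL; x$fits <- NULL
      lapply(x, strip)
    } else x
  }
  rep <- list(
    seed = seed,
    transfer = if (is.null(transfer)) "not run" else strip(unclass(transfer)),
    kinetics = if (is.null(kinetics)) "not run" else strip(unclass(kinetics)),
    crowding = if (is.null(crowding)) "not run" else strip(unclass(crowding))
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    return(invisible(rep))
  }
  rep
}
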