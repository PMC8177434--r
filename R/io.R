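.locality_cols <- c("locality_id", "year", "n_bilinguals", "alpha",
                    "observed_use", "use_kind")

#' Read a locality survey table
#'
#' Reads a delimited text table of locality-level survey rows (one row per
#' locality per survey year) into the canonical schema: `locality_id`,
#' `year`, `n_bilinguals`, `alpha`, `observed_use`, `use_kind`. Column names
#' can be remapped, percentage-coded proportion columns are converted to
#' unit-interval fractions, and rows violating the record invariants
#' (`0 < alpha < 1`, `0 <= observed_use <= 1`, `n_bilinguals >= 0`) are
#' rejected with their line numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Optional named character vector remapping file columns to
#'   canonical names, e.g. `c(municipality = "locality_id", KE =
#'   "observed_use")` maps file column `municipality` to `locality_id`.
#' @param percent_cols If `TRUE`, `alpha` and `observed_use` are read as
#'   percentages and divided by 100. Without this flag, proportion values
#'   above 1 are an error — units are never guessed.
#' @param sep Field separator.
#' @param max_reject_frac Abort when more than this fraction of rows fails
#'   validation.
#' @return Data frame in the canonical schema (valid rows only). Rejected
#'   rows are reported in a warning with line numbers.
#' @export
read_locality_table <- function(path, col_map = NULL, percent_cols = FALSE,
                                sep = ",", max_reject_frac = 0.10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- col_map[names(raw)[hit]]
  }
  missing_cols <- setdiff(.locality_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[.locality_cols]
  for (col in c("alpha", "observed_use", "n_bilinguals", "year")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  if (percent_cols) {
    raw$alpha <- raw$alpha / 100
    raw$observed_use <- raw$observed_use / 100
  } else if (any(raw$alpha > 1 | raw$observed_use > 1, na.rm = TRUE)) {
    stop("proportion values above 1 found; if the table stores percentages, set percent_cols = TRUE",
         call. = FALSE)
  }

  problems <- character(0)
  bad <- logical(nrow(raw))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      # +1 for the header row: report file line numbers
      problems <<- c(problems, sprintf("line %d: %s", which(cond) + 1L, msg))
      bad <<- bad | cond
    }
  }
  flag(is.na(raw$alpha) | raw$alpha <= 0 | raw$alpha >= 1,
       "alpha must lie in (0, 1)")
  flag(is.na(raw$observed_use) | raw$observed_use < 0 | raw$observed_use > 1,
       "observed_use must lie in [0, 1]")
  flag(is.na(raw$n_bilinguals) | raw$n_bilinguals < 0,
       "n_bilinguals must be a nonnegative count")
  flag(is.na(raw$year), "year must be numeric")
  flag(!raw$use_kind %in% c("street", "daily"),
       "use_kind must be 'street' or 'daily'")

  if (mean(bad) > max_reject_frac) {
    stop(sprintf("%d of %d rows invalid (> %.0f%%); aborting. First problems:\n%s",
                 sum(bad), nrow(raw), 100 * max_reject_frac,
                 paste(head(problems, 5L), collapse = "\n")), call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("rejected %d invalid row(s):\n%s", sum(bad),
                    paste(head(problems, 10L), collapse = "\n")),
            call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  out$year <- as.integer(out$year)
  out$n_bilinguals <- as.integer(out$n_bilinguals)
  rownames(out) <- NULL
  out
}

#' Write a locality table in the canonical schema
#'
#' @param records Data frame with the canonical columns.
#' @param path Output path (comma-separated, header row, UTF-8).
#' @return `path`, invisibly.
#' @export
write_locality_table <- function(records, path) {
  stopifnot(all(.locality_cols %in% names(records)))
  write.csv(records[.locality_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
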