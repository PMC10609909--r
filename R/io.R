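#' Write and read a division log
#'
#' The division log has one row per division: appearance date, the timing of
#' each cell-cycle phase and of the whole cycle (days from season start,
#' 0.001-day resolution), the inhibitor amount received from the mother, the
#' G1 growth rate at birth, the inhibitor concentration when the division
#' check is made, and the cell / mother lineage ids.
#'
#' @param result a [simulate_season()] result, or a division-log data frame.
#' @param path file path.
#' @return `write_division_log` returns `path` invisibly;
#'   `read_division_log` returns the data frame.
#' @export
write_division_log <- function(result, path) {
  log <- if (inherits(result, "season_result")) result$division_log
         else result
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_division_log
#' @export
read_division_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cell_id = "character",
                                 mother_id = "character"))
}

#' Write a season summary
#'
#' One-row summary of a simulated season (year, supply, production,
#' simulated and environmental season lengths, termination reason) as CSV
#' or JSON.
#'
#' @param result a [simulate_season()] result.
#' @param path file path; a `.json` extension selects JSON.
#' @return `path`, invisibly.
#' @export
write_season_summary <- function(result, path) {
  row <- list(year = result$year, supply = result$supply_used,
              production = result$production,
              simulated_season_length = result$simulated_season_length,
              env_season_length = result$env_season_length,
              termination_reason = result$termination_reason)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(row, stringsAsFactors = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write per-day kinetics
#'
#' Daily mean G1 rate, mean inhibitor concentration and external growth
#' rate, as CSV (missing values stay empty, not zero).
#'
#' @param result a [simulate_season()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(result, path) {
  utils::write.csv(extract_kinetics(result), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read observed annual cell production
#'
#' CSV with header `year,cells`.
#'
#' @param path file path.
#' @return data frame with columns `year` and `cells`.
#' @export
read_observed_production <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("year", "cells"), names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_observed_production
#' @param observed data frame with columns `year`, `cells`.
#' @export
write_observed_production <- function(observed, path) {
  utils::write.csv(observed[, c("year", "cells")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
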