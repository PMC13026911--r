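#' Read replicate-level qPCR reactions from CSV
#'
#' The shared tabular schema has header `level_id,copies,replicate,cq`: one
#' row per reaction, `copies` the expected copy number per reaction for that
#' dilution level, and an empty `cq` field marking a negative reaction.
#' Rows with `copies = 0` are rejected -- a reaction with no template is a
#' no-template control and should use the dedicated `level_id` `"ntc"`
#' (NTC rows are read but excluded from `copies` validation).
#'
#' @param path Path to a CSV file.
#' @return A validated reaction tibble with columns `level_id` (character),
#'   `copies` (double), `replicate` (integer), `cq` (double, `NA` when
#'   negative).
#' @seealso [write_reactions()], [validate_reactions()]
#' @export
read_reactions <- function(path) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      level_id = readr::col_character(),
      copies = readr::col_double(),
      replicate = readr::col_integer(),
      cq = readr::col_double()
    )
  )
  validate_reactions(tab)
}

#' Write a reaction table to CSV
#'
#' @param reactions Reaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(reactions, path) {
  reactions <- validate_reactions(reactions)
  readr::write_csv(reactions, path, na = "")
  invisible(path)
}

#' Validate a reaction table against the shared schema
#'
#' Checks column presence and types, positivity of `copies` (except for
#' `"ntc"` rows, which must have `copies = 0` and are retained), uniqueness
#' of `(level_id, replicate)` pairs, and finiteness of recorded Cq values.
#' Offending rows are listed in the error message.
#'
#' @param reactions A data frame in the shared schema.
#' @return The validated table as a tibble.
#' @export
validate_reactions <- function(reactions) {
  need <- c("level_id", "copies", "replicate", "cq")
  missing_cols <- setdiff(need, names(reactions))
  if (length(missing_cols) > 0) {
    stop("reaction table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::as_tibble(reactions)[, need]
  tab$level_id <- as.character(tab$level_id)
  tab$copies <- as.numeric(tab$copies)
  tab$replicate <- as.integer(tab$replicate)
  tab$cq <- as.numeric(tab$cq)

  is_ntc <- tolower(tab$level_id) == "ntc"
  bad_copies <- which(!is_ntc & (!is.finite(tab$copies) | tab$copies <= 0))
  if (length(bad_copies) > 0) {
    stop("`copies` must be > 0 (use level_id \"ntc\" with copies = 0 for ",
         "no-template controls); offending row(s): ",
         paste(utils::head(bad_copies, 10), collapse = ", "), call. = FALSE)
  }
  bad_ntc <- which(is_ntc & tab$copies != 0)
  if (length(bad_ntc) > 0) {
    stop("\"ntc\" rows must have copies = 0; offending row(s): ",
         paste(utils::head(bad_ntc, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(tab$level_id, tab$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (level_id, replicate) pair(s); offending row(s): ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  bad_cq <- which(!is.na(tab$cq) & !is.finite(tab$cq))
  if (length(bad_cq) > 0) {
    stop("non-finite Cq in row(s): ",
         paste(utils::head(bad_cq, 10), collapse = ", "), call. = FALSE)
  }
  tab
}

#' Assemble a run configuration
#'
#' Bundles the thresholds shared by the analysis steps, with the
#' conventional defaults: 95% confidence level, 25% linear-scale RSD
#' criterion for quantification, and 5% alpha for the linearity and Grubbs
#' tests.
#'
#' @param ci_level Confidence level for intervals, in `(0, 1)`.
#' @param rsd_threshold LOQ precision criterion (fraction), `> 0`.
#' @param linearity_alpha,grubbs_alpha Test significance levels, in `(0, 1)`.
#' @param efficiency Optional efficiency override used where the curve fit
#'   is unavailable; `NULL` to derive it from the fitted slope.
#' @param seed Optional integer seed for resampling steps.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(ci_level = 0.95, rsd_threshold = 0.25,
                       linearity_alpha = 0.05, grubbs_alpha = 0.05,
                       efficiency = NULL, seed = NULL) {
  for (p in list(ci_level = ci_level, linearity_alpha = linearity_alpha,
                 grubbs_alpha = grubbs_alpha)) {
    if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
      stop("probabilities in the run configuration must lie in (0, 1).",
           call. = FALSE)
    }
  }
  if (length(rsd_threshold) != 1 || !is.finite(rsd_threshold) ||
      rsd_threshold <= 0) {
    stop("`rsd_threshold` must be > 0.", call. = FALSE)
  }
  if (!is.null(efficiency)) check_efficiency(efficiency)
  structure(
    list(ci_level = ci_level, rsd_threshold = rsd_threshold,
         linearity_alpha = linearity_alpha, grubbs_alpha = grubbs_alpha,
         efficiency = efficiency, seed = seed),
    class = "run_config"
  )
}
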