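# Measurement tables: long-format reads, one row per (subject, parameter, reader).

.measurement_columns <- c("subject_id", "cohort", "group", "parameter", "reader",
                          "value", "units", "quality_score", "age_years", "sex")

#' Construct a measurement table from a data frame
#'
#' A measurement table is a long-format data frame with one row per
#' (subject, parameter, reader) read, carrying the measured value, its
#' units, an optional 1-5 Likert image-quality score and subject
#' covariates.  Validation enforces the table invariants: uniqueness of
#' (subject, parameter, reader), positive values (and 0 < RVFAC < 100),
#' and quality scores in 1..5 when present.
#'
#' @param df data frame with columns \code{subject_id, cohort, group,
#'   parameter, reader, value, units, quality_score, age_years, sex}.
#'   Missing optional covariates may be \code{NA}.
#' @param strict if \code{TRUE}, any invariant violation is an error; if
#'   \code{FALSE}, offending rows are dropped with a warning and the number
#'   of dropped rows is recorded in \code{attr(x, "n_dropped")}.
#' @return A \code{measurement_table}: the validated data frame with a
#'   \code{units_registry} attribute (parameter -> unit string) and an
#'   \code{n_dropped} attribute.
#' @export
measurement_table <- function(df, strict = TRUE) {
  missing_cols <- setdiff(setdiff(.measurement_columns, c("units")), names(df))
  if (length(missing_cols)) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"units" %in% names(df)) {
    df$units <- unname(echo_parameter_units()[as.character(df$parameter)])
  }
  df <- df[, .measurement_columns]
  df$subject_id <- as.character(df$subject_id)
  df$parameter <- as.character(df$parameter)
  df$reader <- as.character(df$reader)
  df$value <- as.numeric(df$value)
  df$quality_score <- suppressWarnings(as.integer(df$quality_score))
  df$age_years <- suppressWarnings(as.numeric(df$age_years))

  bad <- rep(FALSE, nrow(df))
  bad_reason <- character(nrow(df))
  flag <- function(which, reason) {
    new <- which & !bad
    bad[new] <<- TRUE
    bad_reason[new] <<- reason
  }
  flag(!df$parameter %in% .valid_parameters(), "unknown parameter")
  flag(is.na(df$value), "missing value")
  flag(!is.na(df$value) & df$value <= 0, "nonpositive value")
  flag(df$parameter == "RVFAC" & !is.na(df$value) & df$value >= 100,
       "RVFAC outside (0, 100)")
  flag(!is.na(df$quality_score) & !(df$quality_score %in% 1:5),
       "quality score outside 1-5")

  key <- paste(df$subject_id, df$parameter, df$reader, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (strict) {
      first <- df[which(dup)[1L], ]
      stop(sprintf("duplicate read for (subject_id=%s, parameter=%s, reader=%s)",
                   first$subject_id, first$parameter, first$reader))
    }
    flag(dup, "duplicate (subject, parameter, reader)")
  }

  if (any(bad)) {
    if (strict) {
      i <- which(bad)[1L]
      stop(sprintf("invalid measurement row %d: %s", i, bad_reason[i]))
    }
    warning(sprintf("dropped %d invalid measurement row(s) (%s)",
                    sum(bad), paste(unique(bad_reason[bad]), collapse = "; ")))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL

  registry <- echo_parameter_units()[intersect(.valid_parameters(),
                                               unique(df$parameter))]
  structure(df,
            units_registry = registry,
            n_dropped = sum(bad),
            class = c("measurement_table", "data.frame"))
}

#' Read a long-format measurement CSV
#'
#' Expects the canonical columns \code{subject_id, cohort, group, parameter,
#' reader, value, units, quality_score, age_years, sex}; missing values are
#' encoded as empty fields (never sentinels such as 0 or -1, since yield
#' accounting depends on correct missingness).
#'
#' @param path path to a CSV file.
#' @param strict reject (error) rather than drop invalid rows; see
#'   \code{\link{measurement_table}}.
#' @return A \code{measurement_table}.
#' @export
read_measurement_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  cls <- setNames(rep("character", 6),
                  c("subject_id", "cohort", "group", "parameter", "reader", "sex"))
  df <- suppressWarnings(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
             colClasses = cls))
  measurement_table(df, strict = strict)
}

#' Write a measurement table to CSV
#'
#' Round-trips exactly through \code{\link{read_measurement_table}}:
#' missing entries become empty fields and full numeric precision is kept.
#'
#' @param x a \code{measurement_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurement_table <- function(x, path) {
  stopifnot(inherits(x, "measurement_table"))
  df <- as.data.frame(x)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("Measurement table: %d reads, %d subjects, %d parameter(s), readers: %s\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$parameter)),
              paste(sort(unique(x$reader)), collapse = ", ")))
  if (attr(x, "n_dropped") > 0)
    cat(sprintf("  (%d invalid row(s) dropped at load)\n", attr(x, "n_dropped")))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a hemodynamics CSV
#'
#' Columns: \code{subject_id, mpap_mmhg, days_echo_to_rhc} (the last one
#' optional).  One row per subject; MPAP must be positive.
#'
#' @param path CSV path.
#' @return data frame with one row per subject.
#' @export
read_hemodynamics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("subject_id", "mpap_mmhg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("hemodynamics table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in hemodynamics table")
  if (any(is.na(df$mpap_mmhg)) || any(df$mpap_mmhg <= 0))
    stop("mpap_mmhg must be present and > 0 for every subject")
  if (!"days_echo_to_rhc" %in% names(df)) df$days_echo_to_rhc <- NA_integer_
  df
}

#' Collapse a 1-5 Likert image-quality score to a category
#'
#' Scores 4-5 are \code{good}, 3 is \code{moderate}, 1-2 are \code{low}.
#'
#' @param score integer vector with values in 1..5.
#' @return factor with levels \code{good, moderate, low}.
#' @export
#' @examples
#' quality_category(c(5, 3, 2))
quality_category <- function(score) {
  score <- as.integer(score)
  out <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  if (any(ok & !(score %in% 1:5)))
    stop("quality score must be in 1..5")
  out[ok & score >= 4] <- "good"
  out[ok & score == 3] <- "moderate"
  out[ok & score <= 2] <- "low"
  factor(out, levels = c("good", "moderate", "low"))
}
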