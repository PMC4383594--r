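#' Declare variable roles for a long-format longitudinal table
#'
#' A long-format table has one row per subject-evaluation. Three columns are
#' mandatory: a subject identifier, a calendar date of evaluation, and an
#' evaluation-occasion label (numeric or categorical). At least one outcome
#' column must be named; outcomes are numeric (e.g. 0-10 visual-analog-scale
#' intensities) or already binary. A binary grouping column may be declared
#' for two-group comparisons.
#'
#' @param id,date,occasion Names of the subject-ID, evaluation-date and
#'   evaluation-occasion columns.
#' @param outcomes Character vector of outcome column names (non-empty).
#' @param covariates Character vector of covariate column names.
#' @param grouping Optional name of a binary grouping column.
#' @param treat_as_binary If `TRUE`, analyses that support a binary mode
#'   dichotomize the outcomes at `threshold`.
#' @param threshold Dichotomization threshold; values strictly greater than
#'   the threshold code 1, values less than or equal code 0 (so threshold 0
#'   on a 0-10 scale encodes symptom presence). Required iff
#'   `treat_as_binary` is `TRUE`.
#' @param occasion_levels Optional explicit order of occasion levels. When
#'   absent, levels that all parse as numbers are sorted numerically,
#'   otherwise first-appearance order is used. The first level is the
#'   baseline/reference.
#' @param date_format Optional `strptime` format for the date column. By
#'   default ISO-8601 (`%Y-%m-%d`) is tried first, then `%d.%m.%Y`.
#' @return An object of class `var_roles`.
#' @export
#' @examples
#' var_roles(id = "PatientID", date = "Date", occasion = "Measurement",
#'           outcomes = c("Fatigue", "Nausea"))
var_roles <- function(id, date, occasion, outcomes,
                      covariates = character(), grouping = NULL,
                      treat_as_binary = FALSE, threshold = NULL,
                      occasion_levels = NULL, date_format = NULL) {
  if (length(outcomes) < 1) {
    abort("`outcomes` must name at least one column.", class = "longmed_role_error")
  }
  if (treat_as_binary && is.null(threshold)) {
    abort("`threshold` is required when `treat_as_binary = TRUE`.",
          class = "longmed_role_error")
  }
  if (!treat_as_binary && !is.null(threshold)) {
    abort("`threshold` is only meaningful with `treat_as_binary = TRUE`.",
          class = "longmed_role_error")
  }
  structure(
    list(id = id, date = date, occasion = occasion,
         outcomes = as.character(outcomes),
         covariates = as.character(covariates),
         grouping = grouping,
         treat_as_binary = isTRUE(treat_as_binary),
         threshold = threshold,
         occasion_levels = occasion_levels,
         date_format = date_format),
    class = "var_roles")
}

#' @export
print.var_roles <- function(x, ...) {
  cat("<var_roles>\n")
  cat("  id:        ", x$id, "\n")
  cat("  date:      ", x$date, "\n")
  cat("  occasion:  ", x$occasion, "\n")
  cat("  outcomes:  ", paste(x$outcomes, collapse = ", "), "\n")
  if (length(x$covariates)) cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (!is.null(x$grouping)) cat("  grouping:  ", x$grouping, "\n")
  if (x$treat_as_binary) cat("  binary at threshold >", x$threshold, "\n")
  invisible(x)
}

#' Read a long-format delimited table
#'
#' Reads a TSV or CSV file with a header row; all columns come back as
#' character so that typing happens under control of [validate_roles()].
#' Empty strings and the literal `NA` are treated as missing.
#'
#' @param path Path to the file.
#' @param delimiter `"tab"`, `"comma"`, or `"auto"` (sniff from the header).
#' @return A tibble of character columns, row order preserved.
#' @export
read_long_table <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- arg_match(delimiter)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "longmed_format_error")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    abort("File is empty: no header row.", class = "longmed_format_error")
  }
  delim <- switch(delimiter,
    tab = "\t", comma = ",",
    auto = if (grepl("\t", header)) "\t" else ",")
  nms <- strsplit(header, delim, fixed = TRUE)[[1]]
  if (anyDuplicated(nms)) {
    abort(paste0("Duplicate column names in header: ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          class = "longmed_format_error")
  }
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE, trim_ws = TRUE)
}

parse_dates <- function(x, date_format = NULL) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  if (!is.null(date_format)) return(as.Date(x, format = date_format))
  out <- as.Date(x, format = "%Y-%m-%d")
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) out[retry] <- as.Date(x[retry], format = "%d.%m.%Y")
  out
}

#' Validate a long table against declared variable roles
#'
#' Checks the structural invariants of the data model: mandatory columns are
#' present and non-missing, `(id, occasion)` pairs are unique, dates parse as
#' calendar dates, outcome columns are numeric, and a declared grouping
#' column has exactly two levels. Occasion levels get a declared order with
#' the first level as baseline.
#'
#' @param data A data frame (typically from [read_long_table()]).
#' @param roles A [var_roles()] object.
#' @return A tibble of class `longitudinal_df` carrying the resolved roles as
#'   an attribute; the occasion column is an ordered factor, the date column
#'   a `Date`, outcomes numeric.
#' @export
validate_roles <- function(data, roles) {
  stopifnot(inherits(roles, "var_roles"))
  data <- as_tibble(data)
  needed <- c(roles$id, roles$date, roles$occasion, roles$outcomes,
              roles$covariates, roles$grouping)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not in data: ", paste(missing_cols, collapse = ", ")),
          class = "longmed_role_error")
  }

  for (col in c(roles$id, roles$occasion)) {
    bad <- which(is.na(data[[col]]) | trimws(as.character(data[[col]])) == "")
    if (length(bad)) {
      abort(paste0("Missing `", col, "` in row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "longmed_validation_error")
    }
  }

  dates <- parse_dates(data[[roles$date]], roles$date_format)
  bad <- which(is.na(dates))
  if (length(bad)) {
    abort(paste0("Unparseable or missing date in row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "longmed_validation_error")
  }
  data[[roles$date]] <- dates

  occ_raw <- as.character(data[[roles$occasion]])
  levels <- roles$occasion_levels
  if (is.null(levels)) {
    uniq <- unique(occ_raw)
    num <- suppressWarnings(as.numeric(uniq))
    levels <- if (!anyNA(num)) uniq[order(num)] else uniq
  }
  unknown <- setdiff(occ_raw, levels)
  if (length(unknown)) {
    abort(paste0("Occasion value(s) outside declared levels: ",
                 paste(unknown, collapse = ", ")),
          class = "longmed_validation_error")
  }
  data[[roles$occasion]] <- factor(occ_raw, levels = levels)
  roles$occasion_levels <- levels

  key <- paste(data[[roles$id]], occ_raw, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    abort(paste0("Duplicate (id, occasion) pair(s) in row(s): ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "longmed_validation_error")
  }

  for (col in roles$outcomes) {
    v <- data[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(ifelse(v %in% c("", "NA"), NA, v)))
      if (any(!is.na(v) & is.na(num))) {
        abort(paste0("Outcome column `", col, "` is not numeric."),
              class = "longmed_type_error")
      }
      v <- num
    }
    if (!is.numeric(v)) {
      abort(paste0("Outcome column `", col, "` is not numeric."),
            class = "longmed_type_error")
    }
    data[[col]] <- v
  }

  for (col in unique(c(roles$covariates, roles$grouping))) {
    v <- data[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (!any(!is.na(v) & is.na(num))) data[[col]] <- num
    }
  }

  if (!is.null(roles$grouping)) {
    g <- data[[roles$grouping]]
    lev <- unique(g[!is.na(g)])
    if (length(lev) != 2) {
      abort(paste0("Grouping column `", roles$grouping, "` must have exactly 2 ",
                   "levels after missing removal, found ", length(lev), "."),
            class = "longmed_role_error")
    }
  }

  structure(data, roles = roles,
            class = c("longitudinal_df", class(data)))
}

#' Extract the roles attached to a validated dataset
#' @param data A `longitudinal_df`.
#' @return The `var_roles` object.
#' @export
roles_of <- function(data) {
  roles <- attr(data, "roles", exact = TRUE)
  if (is.null(roles)) {
    abort("Data carries no variable roles; run `validate_roles()` first.",
          class = "longmed_role_error")
  }
  roles
}

#' Dichotomize a numeric vector at a threshold
#'
#' Strictly-greater rule: values above the threshold code 1, values at or
#' below it code 0, missing stays missing. With threshold 0 on a 0-10
#' symptom-intensity scale this encodes presence/absence of the symptom.
#'
#' @param values Numeric vector.
#' @param threshold Numeric scalar.
#' @return Integer vector of 0/1/NA.
#' @export
#' @examples
#' dichotomize(c(0, 0.1, 5, NA), threshold = 0)
dichotomize <- function(values, threshold) {
  if (!is.numeric(values)) {
    abort("`values` must be numeric.", class = "longmed_type_error")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  as.integer(values > threshold)
}

#' Days since each subject's first evaluation
#'
#' Adds a per-row time offset: the number of whole days between the row's
#' evaluation date and the subject's earliest evaluation date (baseline rows
#' get 0).
#'
#' @param data A `longitudinal_df`.
#' @param col Name of the new column.
#' @return `data` with the offset column appended (roles preserved).
#' @export
add_days_since_first <- function(data, col = "days_since_first") {
  roles <- roles_of(data)
  d <- as_tibble(data)
  day_num <- as.numeric(d[[roles$date]])
  d[[col]] <- day_num - stats::ave(day_num, as.character(d[[roles$id]]), FUN = min)
  structure(d, roles = roles, class = c("longitudinal_df", class(d)))
}

#' Basic overview of a validated dataset
#'
#' Counts of rows, unique subjects and occasions; a histogram of the number
#' of evaluations per subject; per-occasion counts of evaluated subjects and
#' of missing outcome values; group sizes when a grouping role is declared.
#'
#' @param data A `longitudinal_df`.
#' @return An object of class `overview_summary` with a [tidy()] method.
#' @export
data_overview <- function(data) {
  roles <- roles_of(data)
  d <- as_tibble(data)
  n_rows <- nrow(d)
  ids <- d[[roles$id]]
  occ <- d[[roles$occasion]]

  per_subject <- if (n_rows) table(table(ids)) else table(integer())
  evaluations_per_subject <- tibble(
    n_evaluations = as.integer(names(per_subject)),
    n_subjects = as.integer(per_subject))

  per_occ <- if (!nlevels(occ)) {
    tibble(occasion = character(), n_evaluated = integer(),
           n_missing_outcomes = integer())
  } else purrr::map_dfr(levels(occ), function(lev) {
    rows <- d[occ == lev, , drop = FALSE]
    tibble(
      occasion = lev,
      n_evaluated = nrow(rows),
      n_missing_outcomes = sum(is.na(as.matrix(rows[roles$outcomes]))))
  })

  group_counts <- NULL
  if (!is.null(roles$grouping)) {
    g <- d[[roles$grouping]]
    group_counts <- as_tibble(table(group = g[!is.na(g)]), .name_repair = "minimal")
    names(group_counts) <- c("group", "n_subjects_rows")
  }

  structure(
    list(n_rows = n_rows,
         n_subjects = n_distinct(ids),
         n_occasions = nlevels(occ),
         evaluations_per_subject = evaluations_per_subject,
         per_occasion = per_occ,
         group_counts = group_counts),
    class = "overview_summary")
}

#' @export
print.overview_summary <- function(x, ...) {
  cat("Longitudinal data overview\n")
  cat("  observations:    ", x$n_rows, "\n")
  cat("  unique subjects: ", x$n_subjects, "\n")
  cat("  occasions:       ", x$n_occasions, "\n")
  if (nrow(x$evaluations_per_subject)) {
    h <- x$evaluations_per_subject
    cat("  evaluations/subject: ",
        paste(sprintf("%dx:%d", h$n_evaluations, h$n_subjects), collapse = "  "),
        "\n")
  }
  invisible(x)
}

#' @rdname data_overview
#' @param x An `overview_summary`.
#' @param ... Unused.
#' @export
tidy.overview_summary <- function(x, ...) {
  bind_rows(
    tibble(statistic = "n_rows", value = x$n_rows),
    tibble(statistic = "n_subjects", value = x$n_subjects),
    tibble(statistic = "n_occasions", value = x$n_occasions),
    tibble(statistic = paste0("subjects_with_", x$evaluations_per_subject$n_evaluations,
                              "_evaluations"),
           value = x$evaluations_per_subject$n_subjects),
    tibble(statistic = paste0("evaluated_at_", x$per_occasion$occasion),
           value = x$per_occasion$n_evaluated),
    tibble(statistic = paste0("missing_outcomes_at_", x$per_occasion$occasion),
           value = x$per_occasion$n_missing_outcomes),
    if (!is.null(x$group_counts))
      tibble(statistic = paste0("group_", x$group_counts$group),
             value = x$group_counts$n_subjects_rows))
}

#' Write a validated dataset back to disk as TSV
#'
#' Round-trip companion of [read_long_table()]: dates are written ISO-8601,
#' missing values as empty cells.
#'
#' @param data A `longitudinal_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  d <- as_tibble(data)
  roles <- attr(data, "roles", exact = TRUE)
  if (!is.null(roles)) {
    d[[roles$occasion]] <- as.character(d[[roles$occasion]])
    d[[roles$date]] <- format(d[[roles$date]], "%Y-%m-%d")
  }
  readr::write_tsv(d, path, na = "")
  invisible(path)
}

#' Subset a validated dataset to one evaluation occasion
#' @param data A `longitudinal_df`.
#' @param occasion An occasion level (coerced to character).
#' @return A `longitudinal_df` restricted to that occasion.
#' @export
at_occasion <- function(data, occasion) {
  roles <- roles_of(data)
  occasion <- as.character(occasion)
  if (!occasion %in% roles$occasion_levels) {
    abort(paste0("Occasion `", occasion, "` is not a declared level."),
          class = "longmed_validation_error")
  }
  d <- as_tibble(data)
  out <- d[as.character(d[[roles$occasion]]) == occasion, , drop = FALSE]
  structure(out, roles = roles, class = c("longitudinal_df", class(out)))
}
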