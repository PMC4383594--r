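#' Lasagna plot (subject-by-occasion heat map) of one outcome
#'
#' Subjects are rows, evaluation occasions columns, color encodes the
#' outcome value; missing cells are drawn white so dropout patterns stay
#' visible. With `cluster_subjects = TRUE` the rows are rearranged by
#' hierarchical clustering (Euclidean distance, complete linkage) so that
#' subjects with similar trajectories sit together.
#'
#' @param data A `longitudinal_df`.
#' @param outcome Outcome column name.
#' @param cluster_subjects Reorder subjects by [hierarchical_order()].
#' @return A ggplot object; the subject order used is attached as attribute
#'   `subject_order`.
#' @export
plot_lasagna <- function(data, outcome, cluster_subjects = TRUE) {
  roles <- roles_of(data)
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome `", outcome, "` not in data."),
          class = "longmed_role_error")
  }
  d <- as_tibble(data)
  wide <- tidyr::pivot_wider(
    d[c(roles$id, roles$occasion, outcome)],
    names_from = all_of(roles$occasion), values_from = all_of(outcome))
  mat <- as.matrix(wide[-1])
  subjects <- as.character(wide[[1]])
  ord <- seq_along(subjects)
  if (cluster_subjects && length(subjects) > 1) {
    ord <- hierarchical_order(mat, labels = subjects)$leaf_order
  }
  long <- tidyr::pivot_longer(wide, -1, names_to = "occasion",
                              values_to = "value")
  names(long)[1] <- "subject"
  long$subject <- factor(as.character(long$subject),
                         levels = rev(subjects[ord]))
  long$occasion <- factor(long$occasion, levels = roles$occasion_levels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$occasion,
                                          y = .data$subject,
                                          fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = outcome) +
    ggplot2::labs(x = "Evaluation occasion", y = "Subject") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  attr(p, "subject_order") <- subjects[ord]
  p
}

#' Spaghetti (profile) plot of one outcome
#'
#' One line per subject connecting its values over the evaluation
#' occasions. With many subjects the profiles overlap, so a seeded random
#' subset can be drawn instead.
#'
#' @param data A `longitudinal_df`.
#' @param outcome Outcome column name.
#' @param subset_size Optional number of subjects to sample; larger than
#'   the number of subjects means all subjects (with a message).
#' @param seed Integer seed for the subject sample.
#' @return A ggplot object; sampled subjects are attached as attribute
#'   `subjects`.
#' @export
plot_spaghetti <- function(data, outcome, subset_size = NULL, seed = NULL) {
  roles <- roles_of(data)
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome `", outcome, "` not in data."),
          class = "longmed_role_error")
  }
  d <- as_tibble(data)
  d$subject <- as.character(d[[roles$id]])
  subjects <- unique(d$subject)
  if (!is.null(subset_size)) {
    if (subset_size >= length(subjects)) {
      inform("`subset_size` is not smaller than the number of subjects; showing all.")
    } else {
      pick <- function() sample(subjects, subset_size)
      subjects <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
      d <- d[d$subject %in% subjects, , drop = FALSE]
    }
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[roles$occasion]],
                                       y = .data[[outcome]],
                                       group = .data$subject)) +
    ggplot2::geom_line(colour = "grey35", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "Evaluation occasion", y = outcome) +
    ggplot2::theme_minimal()
  attr(p, "subjects") <- subjects
  p
}

#' Boxplot grid of outcomes by evaluation occasion
#'
#' Box-and-whisker plots (1.5 IQR whiskers, outliers as points) for each
#' outcome and occasion, faceted either one panel per outcome
#' (`"outcome_by_occasion"`) or one panel per occasion
#' (`"occasion_by_outcome"`).
#'
#' @param data A `longitudinal_df`.
#' @param outcomes Outcome columns (default: all declared outcomes).
#' @param facet_mode Facet layout, see above.
#' @return A ggplot object.
#' @export
plot_boxplots <- function(data, outcomes = NULL,
                          facet_mode = c("outcome_by_occasion",
                                         "occasion_by_outcome")) {
  facet_mode <- arg_match(facet_mode)
  roles <- roles_of(data)
  outcomes <- outcomes %||% roles$outcomes
  d <- as_tibble(data)
  long <- tidyr::pivot_longer(d[c(roles$occasion, outcomes)],
                              all_of(outcomes),
                              names_to = "outcome", values_to = "value")
  long$outcome <- factor(long$outcome, levels = outcomes)
  if (facet_mode == "outcome_by_occasion") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[roles$occasion]],
                                       y = .data$value)) +
      ggplot2::geom_boxplot(na.rm = TRUE) +
      ggplot2::facet_wrap(~outcome) +
      ggplot2::labs(x = "Evaluation occasion", y = "Value") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$value)) +
      ggplot2::geom_boxplot(na.rm = TRUE) +
      ggplot2::facet_wrap(ggplot2::vars(.data[[roles$occasion]])) +
      ggplot2::labs(x = NULL, y = "Value") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         hjust = 1))
  }
}

#' Timeline bubble plot of selected outcomes
#'
#' One horizontal band per subject; each observation is a bubble whose area
#' is proportional to the outcome value (zero values draw no bubble). The
#' horizontal axis can show the calendar date, the evaluation occasion, or
#' the number of days since the subject's first evaluation.
#'
#' @param data A `longitudinal_df`.
#' @param outcomes Outcome columns to display (default: all).
#' @param x_axis `"days_since_first"`, `"occasion"` or `"date"`.
#' @return A ggplot object.
#' @export
plot_timeline <- function(data, outcomes = NULL,
                          x_axis = c("days_since_first", "occasion", "date")) {
  x_axis <- arg_match(x_axis)
  roles <- roles_of(data)
  outcomes <- outcomes %||% roles$outcomes
  d <- as_tibble(add_days_since_first(data, col = ".days"))
  d$subject <- as.character(d[[roles$id]])
  xcol <- switch(x_axis, days_since_first = ".days",
                 occasion = roles$occasion, date = roles$date)
  long <- tidyr::pivot_longer(d[c("subject", xcol, outcomes)],
                              all_of(outcomes),
                              names_to = "outcome", values_to = "value")
  long <- long[!is.na(long$value) & long$value > 0, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xcol]], y = .data$subject,
                                     size = .data$value)) +
    ggplot2::geom_point(colour = "#35608D") +
    ggplot2::scale_size_area(max_size = 4, name = "Value") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = switch(x_axis,
                             days_since_first = "Days since first evaluation",
                             occasion = "Evaluation occasion",
                             date = "Date"),
                  y = "Subject") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Clustered heat map of all outcomes at one occasion
#'
#' Displays every subject (columns) by every outcome (rows) at one
#' evaluation occasion, with both axes rearranged by their own
#' hierarchical clustering (Euclidean distance, complete linkage). Missing
#' cells are white.
#'
#' @param data A `longitudinal_df`.
#' @param occasion Occasion level.
#' @return A ggplot object; orderings attached as attributes
#'   `subject_order` and `outcome_order`.
#' @export
plot_heatmap <- function(data, occasion) {
  roles <- roles_of(data)
  d <- as_tibble(at_occasion(data, occasion))
  if (nrow(d) < 2 || length(roles$outcomes) < 2) {
    abort("Need at least 2 subjects and 2 outcomes at the occasion.",
          class = "longmed_validation_error")
  }
  mat <- as.matrix(d[roles$outcomes])
  subjects <- as.character(d[[roles$id]])
  sub_ord <- hierarchical_order(mat, labels = subjects)$leaf_order
  out_ord <- hierarchical_order(t(mat), labels = roles$outcomes)$leaf_order
  long <- tidyr::pivot_longer(
    cbind(tibble(subject = subjects), as_tibble(mat)),
    -"subject", names_to = "outcome", values_to = "value")
  long$subject <- factor(long$subject, levels = subjects[sub_ord])
  long$outcome <- factor(long$outcome, levels = rev(roles$outcomes[out_ord]))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$subject,
                                          y = .data$outcome,
                                          fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Value") +
    ggplot2::labs(x = "Subject", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  attr(p, "subject_order") <- subjects[sub_ord]
  attr(p, "outcome_order") <- roles$outcomes[out_ord]
  p
}

#' Bar plot of positive-outcome proportions per occasion
#'
#' For binary (or dichotomized) outcomes: the proportion of subjects with a
#' positive outcome at each evaluation occasion.
#'
#' @param data A `longitudinal_df`.
#' @param outcomes Outcome columns (default: all declared outcomes).
#' @param threshold Dichotomization threshold (default: roles' threshold,
#'   else 0).
#' @return A ggplot object.
#' @export
plot_bars <- function(data, outcomes = NULL, threshold = NULL) {
  roles <- roles_of(data)
  outcomes <- outcomes %||% roles$outcomes
  if (is.null(threshold)) {
    threshold <- if (!is.null(roles$threshold)) roles$threshold else 0
  }
  s <- summarize_outcomes(data, binary = TRUE, threshold = threshold)
  s <- s[s$outcome %in% outcomes, , drop = FALSE]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$occasion, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#35608D") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "Evaluation occasion",
                  y = "Proportion with positive outcome") +
    ggplot2::theme_minimal()
}

#' Save a figure as raster plus vector output
#'
#' Writes the plot once per requested format; PNG for raster, EPS or SVG
#' (or PDF) for vector output.
#'
#' @param plot A ggplot object.
#' @param path_base Output path without extension.
#' @param formats Character vector among `"png"`, `"eps"`, `"svg"`,
#'   `"pdf"`.
#' @param width,height,dpi Device settings in inches / dots per inch.
#' @return Character vector of the files written, invisibly.
#' @export
write_figure <- function(plot, path_base, formats = c("png", "eps"),
                         width = 7, height = 5, dpi = 150) {
  bad <- setdiff(formats, c("png", "eps", "svg", "pdf"))
  if (length(bad)) {
    abort(paste0("Unsupported figure format(s): ", paste(bad, collapse = ", ")),
          class = "longmed_usage_error")
  }
  dir <- dirname(path_base)
  if (!dir.exists(dir)) {
    abort(paste0("Directory does not exist: ", dir), class = "longmed_io_error")
  }
  files <- character()
  for (fmt in formats) {
    f <- paste0(path_base, ".", fmt)
    if (fmt == "eps") {
      grDevices::postscript(f, width = width, height = height,
                            horizontal = FALSE, onefile = FALSE,
                            paper = "special")
      print(plot)
      grDevices::dev.off()
    } else {
      suppressMessages(ggplot2::ggsave(f, plot = plot, width = width,
                                       height = height, dpi = dpi))
    }
    files <- c(files, f)
  }
  invisible(files)
}
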