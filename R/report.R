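#' Learning-curve figure
#'
#' Group mean +/- SEM of a per-session metric across phases.
#'
#' @param metrics Per-session metrics tibble.
#' @param metric Column to plot (`"probability"`, `"amplitude"`,
#'   `"percent_cr"`).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(metrics, metric = "probability") {
  summ <- metrics |>
    dplyr::group_by(.data$group, .data$phase, .data$session) |>
    dplyr::summarise(m = mean(.data[[metric]], na.rm = TRUE),
                     sem = stats::sd(.data[[metric]], na.rm = TRUE) /
                       sqrt(sum(!is.na(.data[[metric]]))),
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$m))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$session, y = .data$m,
                                     colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$sem,
                                      ymax = .data$m + .data$sem,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(. ~ phase, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "session", y = metric) +
    ggplot2::theme_minimal()
}

#' Decomposition histogram figure
#'
#' Non-response (reflected) and response distributions of one session, with
#' the fixed %CR threshold marked.
#'
#' @param decomposition A `blink_decomposition`.
#' @param cr_threshold Threshold line position.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition, cr_threshold = 0.15) {
  d <- tibble::tibble(
    center = rep(decomposition$centers, 2),
    mass = c(decomposition$nonresponse_mass, decomposition$response_mass),
    component = rep(c("non-response", "response"),
                    each = length(decomposition$centers)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$center, y = .data$mass,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7,
                      width = decomposition$bin_width) +
    ggplot2::geom_vline(xintercept = cr_threshold, colour = "red") +
    ggplot2::scale_fill_manual(values = c("non-response" = "grey60",
                                          "response" = "black")) +
    ggplot2::labs(x = "normalized peak amplitude", y = "trials") +
    ggplot2::theme_minimal()
}

#' Render a human-readable run report
#'
#' Writes learning-curve figures (probability and amplitude vs session), a
#' representative decomposition histogram, and a text block of the
#' statistical results in the field's reporting style
#' ("F(df1, df2) = ..., p = ...").
#'
#' @param result An `eyeblink_run` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly. Files: `learning_probability.pdf`,
#'   `learning_amplitude.pdf`, `decomposition_example.pdf`, `report.txt`.
#' @export
render_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ggplot2::ggsave(file.path(out_dir, "learning_probability.pdf"),
                  plot_learning_curves(result$metrics, "probability"),
                  width = 7, height = 3.5)
  ggplot2::ggsave(file.path(out_dir, "learning_amplitude.pdf"),
                  plot_learning_curves(result$metrics, "amplitude"),
                  width = 7, height = 3.5)
  # representative decomposition: a late-acquisition session of the first
  # subject
  coh <- result$cohort
  if (!is.null(coh$norm)) {
    tr <- coh$trials
    subj <- tr$subject[1]
    sess <- max(tr$session[tr$subject == subj &
                             tr$phase == "acquisition"])
    rows <- which(tr$subject == subj & tr$phase == "acquisition" &
                    tr$session == sess)
    samp <- collect_peak_amplitudes(coh$norm[rows, , drop = FALSE],
                                    coh$time_ms, tr[rows, ])
    dec <- reflect_and_decompose(build_histogram(samp))
    ggplot2::ggsave(file.path(out_dir, "decomposition_example.pdf"),
                    plot_decomposition(dec), width = 5, height = 3.5)
  }
  writeLines(format_stats_report(result$stats),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

format_stats_report <- function(stats_list) {
  if (!length(stats_list)) return("No group comparisons (single group).")
  lines <- character()
  fmt_p <- function(p) ifelse(p < 0.001, "p < 0.001",
                              sprintf("p = %.3f", p))
  if (!is.null(stats_list$rm_anova_probability)) {
    a <- stats_list$rm_anova_probability
    lines <- c(lines, "Two-way repeated-measures ANOVA (probability):",
               sprintf("  %s: F(%d, %d) = %.2f, %s", a$effect,
                       a$df1, a$df2, a$statistic, fmt_p(a$p_value)))
  }
  if (!is.null(stats_list$last_four_t)) {
    t <- stats_list$last_four_t
    lines <- c(lines,
               "Last-four-session probability (unpaired two-sample t):",
               sprintf("  %s: t(%d) = %.2f, %s, d' = %.2f", t$effect,
                       round(t$df2), t$statistic, fmt_p(t$p_value),
                       t$cohens_d))
  }
  if (!is.null(stats_list$savings)) {
    s <- stats_list$savings
    lines <- c(lines, "Extinction / savings (paired t):",
               sprintf("  %s, %s: n = %d, t(%s) = %s, %s%s",
                       s$group, s$comparison, s$n,
                       ifelse(is.na(s$df), "-", round(s$df)),
                       ifelse(is.na(s$statistic), "-",
                              sprintf("%.2f", s$statistic)),
                       ifelse(is.na(s$p_value), "skipped",
                              fmt_p(s$p_value)),
                       ifelse(s$skipped, " (never acquired)", "")))
  }
  lines
}
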