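#' Assemble per-subject learning curves
#'
#' Orders the per-session metrics table by subject, phase and session,
#' checks for duplicate cells, and flags (without imputing) missing
#' sessions.
#'
#' @param metrics A per-session metrics tibble (see [decompose_cohort()]);
#'   must contain `subject`, `phase`, `session` and at least one of
#'   `probability`, `amplitude`, `percent_cr`.
#' @return The ordered tibble, with an attribute `missing_sessions` listing
#'   gaps in the per-phase session sequence.
#' @export
build_learning_curves <- function(metrics) {
  need <- c("subject", "phase", "session")
  if (!all(need %in% names(metrics)))
    stopf("metrics table must contain columns %s",
          paste(need, collapse = ", "))
  key <- paste(metrics$subject, metrics$phase, metrics$session)
  if (anyDuplicated(key))
    stopf("duplicate (subject, phase, session) rows in metrics table")
  out <- dplyr::arrange(metrics, .data$subject, .data$phase, .data$session)
  gaps <- out |>
    dplyr::group_by(.data$subject, .data$phase) |>
    dplyr::summarise(
      missing = list(setdiff(seq_len(max(.data$session)), .data$session)),
      .groups = "drop") |>
    dplyr::filter(lengths(.data$missing) > 0)
  if (nrow(gaps))
    warning(sprintf("%d subject-phase cells have missing sessions", nrow(gaps)),
            call. = FALSE)
  attr(out, "missing_sessions") <- gaps
  out
}

#' Mean over the last four sessions of a phase
#'
#' The standard end-of-training summary: per subject, the arithmetic mean of
#' the phase's final four sessions.
#'
#' @param curves Output of [build_learning_curves()] (or any per-session
#'   metrics tibble).
#' @param phase Phase to summarize.
#' @param n_last Number of trailing sessions (default 4).
#' @return A tibble with one row per subject: `subject`, `group` (if
#'   present), and the means of `probability`, `amplitude`, `percent_cr`
#'   over the trailing sessions.
#' @export
last_four_mean <- function(curves, phase = "acquisition", n_last = 4L) {
  dat <- dplyr::filter(curves, .data$phase == !!phase)
  if (!nrow(dat)) stopf("no rows for phase '%s'", phase)
  n_sess <- max(dat$session)
  if (n_sess < n_last)
    stopf("phase '%s' has %d sessions; %d required", phase, n_sess, n_last)
  keep <- dat$session > n_sess - n_last
  dat <- dat[keep, ]
  grp_cols <- intersect(c("subject", "group", "age_days"), names(dat))
  val_cols <- intersect(c("probability", "amplitude", "percent_cr"),
                        names(dat))
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(val_cols),
                                   \(x) mean(x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Cohen's d (pooled-SD effect size)
#'
#' `|mean_a - mean_b| / s_pooled`, where the pooled SD uses
#' Bessel-corrected group SDs:
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return The effect size (non-negative scalar).
#' @export
cohens_dprime <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 <= 0) stopf("pooled SD is zero; effect size undefined")
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Two-way mixed-design (repeated-measures) ANOVA
#'
#' Genotype (between subjects) x session (within subjects), the design used
#' for the time-course comparisons: classical univariate mixed ANOVA with
#' the between-group effect tested against the subject-within-group mean
#' square and the within effects against the subject x session residual.
#' Session is treated as categorical and no sphericity correction is
#' applied (uncorrected F and df are reported). Subjects with missing
#' sessions are dropped listwise with a warning.
#'
#' @param data A tibble with columns `subject`, `group`, `session`, and the
#'   response named by `response`.
#' @param response Name of the response column.
#' @return A `group_comparison` tibble with one row per effect
#'   (`group`, `session`, `group:session`): `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_2way <- function(data, response = "probability") {
  need <- c("subject", "group", "session", response)
  if (!all(need %in% names(data)))
    stopf("data must contain columns %s", paste(need, collapse = ", "))
  d <- data.frame(subject = factor(data$subject),
                  group = factor(as.character(data$group)),
                  session = factor(data$session),
                  y = data[[response]])
  d <- d[stats::complete.cases(d), ]
  n_sess <- length(unique(d$session))
  counts <- table(d$subject)
  bad <- names(counts)[counts < n_sess]
  if (length(bad)) {
    warning(sprintf("dropping %d subject(s) with missing sessions", length(bad)),
            call. = FALSE)
    d <- d[!d$subject %in% bad, ]
    d$subject <- droplevels(d$subject)
  }
  if (length(unique(d$group)) < 2) stopf("need >= 2 groups")
  fit <- stats::aov(y ~ group * session + Error(subject), data = d)
  sm <- summary(fit)
  betw <- sm[["Error: subject"]][[1]]
  with <- sm[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  pick <- function(tab, term) {
    i <- match(term, rn(tab))
    resid <- match("Residuals", rn(tab))
    c(df1 = tab$Df[i], df2 = tab$Df[resid], F = tab$`F value`[i],
      p = tab$`Pr(>F)`[i])
  }
  res <- rbind(group = pick(betw, "group"),
               session = pick(with, "session"),
               `group:session` = pick(with, "group:session"))
  out <- tibble::tibble(effect = rownames(res),
                        df1 = as.numeric(res[, "df1"]),
                        df2 = as.numeric(res[, "df2"]),
                        statistic = as.numeric(res[, "F"]),
                        p_value = as.numeric(res[, "p"]))
  attr(out, "design") <- "rm_anova_2way"
  class(out) <- c("group_comparison", class(out))
  out
}

#' One-way ANOVA with Bonferroni-adjusted planned comparisons
#'
#' Omnibus one-way ANOVA followed by planned pairwise comparisons using the
#' pooled error term; each raw p-value is multiplied by the number of
#' planned comparisons (capped at 1).
#'
#' @param values Numeric response vector.
#' @param group Group labels (same length as `values`).
#' @param planned_pairs A list of length-2 character vectors naming the
#'   planned comparisons; default: all pairs.
#' @return A `group_comparison` tibble: the omnibus row
#'   (`effect = "omnibus"`) plus one row per planned pair with the pooled-SE
#'   t statistic, raw and Bonferroni-adjusted p, and Cohen's d.
#' @export
oneway_anova_bonferroni <- function(values, group, planned_pairs = NULL) {
  group <- factor(as.character(group))
  if (nlevels(group) < 2) stopf("need >= 2 groups")
  if (any(table(group) < 2)) stopf("each group needs n >= 2")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  mse <- tab$`Mean Sq`[2]
  df_resid <- tab$Df[2]
  if (is.null(planned_pairs))
    planned_pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  m <- length(planned_pairs)
  rows <- lapply(planned_pairs, function(pr) {
    a <- values[group == pr[1]]; b <- values[group == pr[2]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tstat <- (mean(a) - mean(b)) / se
    praw <- 2 * stats::pt(-abs(tstat), df_resid)
    tibble::tibble(effect = paste(pr, collapse = " vs "),
                   df1 = NA_real_, df2 = df_resid, statistic = tstat,
                   p_value = min(1, m * praw), p_raw = praw,
                   cohens_d = cohens_dprime(a, b))
  })
  out <- dplyr::bind_rows(
    tibble::tibble(effect = "omnibus", df1 = tab$Df[1], df2 = df_resid,
                   statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                   p_raw = tab$`Pr(>F)`[1], cohens_d = NA_real_),
    dplyr::bind_rows(rows))
  attr(out, "design") <- "oneway_anova_bonferroni"
  class(out) <- c("group_comparison", class(out))
  out
}

#' ANCOVA with age as covariate and Tukey HSD post hoc tests
#'
#' Group effect adjusted for a common linear age slope
#' (`y ~ age + group`; the group test is the F for adding group to the
#' age-only model), followed by Tukey HSD contrasts on the adjusted group
#' means. When age is constant the model reduces to a one-way ANOVA (the
#' covariate column is dropped, not an error).
#'
#' @param data A tibble with columns `group`, `age_days`, and the response
#'   named by `response`.
#' @param response Name of the response column.
#' @return A `group_comparison` tibble: the adjusted group effect row plus
#'   one row per Tukey contrast.
#' @export
ancova_age_tukey <- function(data, response = "probability") {
  need <- c("group", "age_days", response)
  if (!all(need %in% names(data)))
    stopf("data must contain columns %s", paste(need, collapse = ", "))
  d <- data.frame(group = factor(as.character(data$group)),
                  age_days = data$age_days, y = data[[response]])
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$group)) < 2) stopf("need >= 2 groups")
  d$group <- droplevels(d$group)
  const_age <- stats::sd(d$age_days) == 0
  if (const_age) {
    fit <- stats::lm(y ~ group, data = d)
    null_fit <- stats::lm(y ~ 1, data = d)
  } else {
    fit <- stats::lm(y ~ age_days + group, data = d)
    null_fit <- stats::lm(y ~ age_days, data = d)
  }
  an <- stats::anova(null_fit, fit)
  grp_row <- tibble::tibble(effect = "group (age-adjusted)",
                            df1 = an$Df[2], df2 = an$Res.Df[2],
                            statistic = an$F[2], p_value = an$`Pr(>F)`[2])
  tk <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  ts <- summary(tk)$test
  tuk <- tibble::tibble(effect = names(ts$coefficients),
                        df1 = NA_real_, df2 = stats::df.residual(fit),
                        statistic = as.numeric(ts$tstat),
                        p_value = as.numeric(ts$pvalues))
  out <- dplyr::bind_rows(grp_row, tuk)
  attr(out, "design") <- "ancova_age_tukey"
  class(out) <- c("group_comparison", class(out))
  out
}

#' Extinction and savings paired comparisons
#'
#' Per group: paired t-tests of the %CR on the last acquisition session vs
#' the last extinction session (extinction of the CR), and the last
#' extinction session vs the last reacquisition session (savings). Groups
#' flagged as never having acquired (`skip_groups`) are reported but
#' skipped, and subjects missing any of the three phases are excluded with
#' a warning.
#'
#' @param curves Per-session metrics with `subject`, `group`, `phase`,
#'   `session`, `percent_cr`.
#' @param skip_groups Labels of groups that never acquired CRs.
#' @return A tibble with one row per group x comparison: `group`,
#'   `comparison`, `n`, `mean_diff`, `statistic` (paired t), `df`,
#'   `p_value`, `skipped`.
#' @export
savings_summary <- function(curves, skip_groups = character()) {
  need <- c("subject", "group", "phase", "session", "percent_cr")
  if (!all(need %in% names(curves)))
    stopf("curves must contain columns %s", paste(need, collapse = ", "))
  last_of <- function(ph) {
    curves |>
      dplyr::filter(.data$phase == ph) |>
      dplyr::group_by(.data$subject, .data$group) |>
      dplyr::filter(.data$session == max(.data$session)) |>
      dplyr::ungroup() |>
      dplyr::select("subject", "group", value = "percent_cr")
  }
  acq <- last_of("acquisition"); ext <- last_of("extinction")
  rea <- last_of("reacquisition")
  complete <- Reduce(intersect, list(acq$subject, ext$subject, rea$subject))
  dropped <- setdiff(unique(curves$subject), complete)
  if (length(dropped))
    warning(sprintf("excluding %d subject(s) missing a phase", length(dropped)),
            call. = FALSE)
  pairs <- list(
    acquisition_vs_extinction = list(a = acq, b = ext),
    extinction_vs_reacquisition = list(a = ext, b = rea))
  rows <- list()
  for (g in unique(curves$group)) {
    subj <- intersect(complete, acq$subject[acq$group == g])
    for (cmp in names(pairs)) {
      a <- pairs[[cmp]]$a; b <- pairs[[cmp]]$b
      av <- a$value[match(subj, a$subject)]
      bv <- b$value[match(subj, b$subject)]
      skipped <- g %in% skip_groups
      if (!skipped && length(subj) >= 2 && stats::sd(av - bv) > 0) {
        tt <- stats::t.test(av, bv, paired = TRUE)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = g, comparison = cmp, n = length(subj),
          mean_diff = mean(av - bv),
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, skipped = FALSE)
      } else {
        md <- if (length(subj)) mean(av - bv) else NA_real_
        degenerate <- !skipped && length(subj) >= 2
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = g, comparison = cmp, n = length(subj),
          mean_diff = md,
          statistic = if (degenerate && md == 0) 0 else NA_real_,
          df = if (degenerate) length(subj) - 1 else NA_real_,
          p_value = if (degenerate) { if (md == 0) 1 else 0 } else NA_real_,
          skipped = skipped)
      }
    }
  }
  dplyr::bind_rows(rows)
}
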