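#' Matched pair of condition values per experimental unit
#'
#' @param unit Unit (animal) identifiers.
#' @param a,b Condition values, matched by position to `unit`.
#' @return A `paired_sample` object.
#' @export
paired_sample <- function(unit, a, b) {
  n <- length(unit)
  if (n < 2L) stop_field("unit", "needs at least 2 units")
  if (length(a) != n || length(b) != n) {
    stop_field("a", "condition vectors must match unit length")
  }
  if (anyDuplicated(unit)) stop_field("unit", "duplicate unit ids")
  structure(list(unit = as.character(unit), a = as.numeric(a),
                 b = as.numeric(b)),
            class = "paired_sample")
}

#' Two-tailed paired t-test
#'
#' Computes the per-unit differences `d = a - b`, then
#' `t = mean(d) / (sd(d) / sqrt(n))` with the n-1 sample SD, `df = n - 1`,
#' and the two-tailed p-value from the t distribution. Identical to the
#' one-sample t of the differences against zero.
#'
#' @param sample A [paired_sample()].
#' @return A `stat_result` list: `statistic`, `df`, `p_raw`,
#'   `p_adjusted` (NA until adjusted), `m`, `mean_diff`.
#' @export
paired_t <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- sample$a - sample$b
  n <- length(d)
  s <- stats::sd(d)
  md <- mean(d)
  if (s == 0) {
    if (md == 0) {
      return(stat_result(statistic = 0, df = n - 1, p_raw = 1))
    }
    stop("all differences identical with nonzero mean: t is infinite",
         call. = FALSE)
  }
  tval <- md / (s / sqrt(n))
  stat_result(statistic = tval, df = n - 1,
              p_raw = 2 * stats::pt(-abs(tval), df = n - 1),
              mean_diff = md)
}

stat_result <- function(statistic, df, p_raw, p_adjusted = NA_real_,
                        m = 1L, mean_diff = NA_real_, label = NULL) {
  structure(list(statistic = statistic, df = df, p_raw = p_raw,
                 p_adjusted = p_adjusted, m = m, mean_diff = mean_diff,
                 label = label),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(x$label, ": ")
  cat(sprintf("%st(%s) = %.4g, p = %.4g%s\n", lab,
              paste(signif(x$df, 6), collapse = ","), x$statistic, x$p_raw,
              if (!is.na(x$p_adjusted)) {
                sprintf(" (Sidak-adjusted %.4g, m = %d)", x$p_adjusted, x$m)
              } else ""))
  invisible(x)
}

#' Two-way mixed (repeated-measures) ANOVA
#'
#' Classical decomposition for one between-subjects factor (`group`) and
#' one within-subjects factor (`within`), complete data, no sphericity
#' correction: the group effect is tested against the subjects-within-
#' groups mean square; the within-factor and interaction effects against
#' the within-subjects error mean square. Group sizes may differ; every
#' subject must be observed at every within level exactly once.
#'
#' @param data Long-format data frame.
#' @param unit,group,within,value Column names (strings).
#' @return An `anova_table`: data frame of effects (SS, df, MS, F, p) plus
#'   attributes used by [sidak_posthoc()].
#' @export
mixed_rm_anova <- function(data, unit = "unit", group = "group",
                           within = "within", value = "value") {
  stopifnot(is.data.frame(data),
            all(c(unit, group, within, value) %in% names(data)))
  u <- as.character(data[[unit]])
  g <- as.character(data[[group]])
  w <- as.character(data[[within]])
  y <- as.numeric(data[[value]])

  # one group per unit
  ug <- unique(data.frame(u = u, g = g))
  if (anyDuplicated(ug$u)) {
    stop("each unit must belong to exactly one group", call. = FALSE)
  }
  levels_w <- sort(unique(w))
  n_w <- length(levels_w)
  tab <- table(u, w)
  if (any(tab != 1L)) {
    stop("design incomplete: every unit must be observed once at every within level",
         call. = FALSE)
  }

  groups <- sort(unique(g))
  n_g <- length(groups)
  units_per_group <- vapply(groups, function(gi) sum(ug$g == gi), numeric(1))
  n_units <- sum(units_per_group)

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  subj_mean <- tapply(y, u, mean)
  group_of_unit <- ug$g[match(names(subj_mean), ug$u)]
  group_mean <- tapply(y, g, mean)[groups]
  level_mean <- tapply(y, w, mean)[levels_w]
  cell_mean <- tapply(y, list(g, w), mean)[groups, levels_w, drop = FALSE]

  ss_group <- n_w * sum(units_per_group * (group_mean - grand)^2)
  ss_subj_total <- n_w * sum((subj_mean - grand)^2)
  ss_subj_within <- ss_subj_total - ss_group
  ss_within_lvl <- n_units * sum((level_mean - grand)^2)
  ss_cells <- 0
  for (i in seq_len(n_g)) {
    ss_cells <- ss_cells + unname(units_per_group[i]) *
      sum((cell_mean[i, ] - grand)^2)
  }
  ss_inter <- ss_cells - ss_group - ss_within_lvl
  ss_error <- ss_total - ss_cells - ss_subj_within

  df_group <- n_g - 1
  df_subj <- n_units - n_g
  df_within <- n_w - 1
  df_inter <- df_group * df_within
  df_error <- df_subj * df_within

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_group <- ms(ss_group, df_group)
  ms_subj <- ms(ss_subj_within, df_subj)
  ms_within <- ms(ss_within_lvl, df_within)
  ms_inter <- ms(ss_inter, df_inter)
  ms_error <- ms(ss_error, df_error)

  fr <- function(ms_eff, ms_err) {
    if (is.na(ms_eff) || is.na(ms_err) || ms_err <= 0) return(NA_real_)
    ms_eff / ms_err
  }
  f_group <- fr(ms_group, ms_subj)
  f_within <- fr(ms_within, ms_error)
  f_inter <- fr(ms_inter, ms_error)
  pv <- function(f, df1, df2) {
    if (is.na(f)) NA_real_ else stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  tbl <- data.frame(
    effect = c("group", "within", "group:within",
               "subjects_within_groups", "error_within"),
    ss = c(ss_group, ss_within_lvl, ss_inter, ss_subj_within, ss_error),
    df = c(df_group, df_within, df_inter, df_subj, df_error),
    ms = c(ms_group, ms_within, ms_inter, ms_subj, ms_error),
    f = c(f_group, f_within, f_inter, NA, NA),
    p = c(pv(f_group, df_group, df_subj),
          pv(f_within, df_within, df_error),
          pv(f_inter, df_inter, df_error), NA, NA))
  structure(tbl,
            class = c("anova_table", "data.frame"),
            ss_total = ss_total,
            cell_means = cell_mean,
            units_per_group = stats::setNames(units_per_group, groups),
            levels_within = levels_w,
            ms_error = ms_error,
            df_error = df_error)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (no sphericity correction)\n")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adjusted = 1 - (1 - p_raw)^m`, clipped to `[0, 1]`.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p_raw, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    stop_field("m", "must be an integer >= 1")
  }
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop_field("p_raw", "must lie in [0, 1]")
  }
  pmin(1, pmax(0, 1 - (1 - p_raw)^m))
}

#' Sidak post-hoc within-level contrasts per group
#'
#' After a significant interaction, contrasts two within-subject levels
#' inside each group using the ANOVA within-error mean square as the
#' pooled variance estimate:
#' `t = (mean_l1 - mean_l2) / sqrt(2 * MS_error / n_group)` on the
#' within-error degrees of freedom (so all groups share one df, e.g.
#' t(31) for 34 units in 3 groups with 2 levels). Raw p-values are
#' Sidak-adjusted with `m` = number of groups.
#'
#' @param fit A [mixed_rm_anova()] result.
#' @param levels Length-2 character vector naming the two within levels to
#'   contrast (default: the first two).
#' @return List of `stat_result`, one per group.
#' @export
sidak_posthoc <- function(fit, levels = NULL) {
  stopifnot(inherits(fit, "anova_table"))
  cm <- attr(fit, "cell_means")
  npg <- attr(fit, "units_per_group")
  lw <- attr(fit, "levels_within")
  ms_err <- attr(fit, "ms_error")
  df_err <- attr(fit, "df_error")
  if (is.null(levels)) levels <- lw[1:2]
  if (!all(levels %in% lw)) stop_field("levels", "unknown within level")
  m <- nrow(cm)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    diff <- unname(cm[i, levels[1]] - cm[i, levels[2]])
    se <- sqrt(2 * ms_err / unname(npg[i]))
    tval <- diff / se
    p_raw <- 2 * stats::pt(-abs(tval), df = df_err)
    out[[i]] <- stat_result(statistic = tval, df = df_err, p_raw = p_raw,
                            p_adjusted = sidak_adjust(p_raw, m), m = m,
                            mean_diff = diff, label = rownames(cm)[i])
  }
  names(out) <- rownames(cm)
  out
}
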