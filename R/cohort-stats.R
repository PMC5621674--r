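#' Construct a cohort metric table
#'
#' Long-format table of per-specimen stiffness metrics: one row per
#' (specimen, region, range) with the metric value in kJ/m^3.
#'
#' @param df A `data.frame` with columns `specimen`, `region` (LV/RV/OFT),
#'   `group` (control/mutant), `range` (0.2 or 0.4) and `value`.
#' @return The validated `data.frame` with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  need <- c("specimen", "region", "group", "range", "value")
  if (!all(need %in% names(df)))
    pa_stop(sprintf("cohort table lacks columns %s",
                    paste(setdiff(need, names(df)), collapse = ", ")),
            "pamech_invalid_table")
  if (any(!is.finite(df$value)))
    pa_stop("metric values must be finite", "pamech_invalid_table")
  key <- paste(df$specimen, df$region, df$range, sep = "\r")
  if (anyDuplicated(key))
    pa_stop("duplicate (specimen, region, range) keys", "pamech_invalid_table")
  class(df) <- c("cohort_table", class(df))
  df
}

#' Convert a per-test SED summary to a long cohort table
#'
#' @param summary_df Output of [sed_table()] / rows of [sed_summary()].
#' @return A [cohort_table] with ranges 0.2 and 0.4.
#' @export
as_cohort_table <- function(summary_df) {
  long <- rbind(
    data.frame(specimen = summary_df$specimen, region = summary_df$region,
               group = summary_df$group, range = 0.2, value = summary_df$sed_02,
               stringsAsFactors = FALSE),
    data.frame(specimen = summary_df$specimen, region = summary_df$region,
               group = summary_df$group, range = 0.4, value = summary_df$sed_04,
               stringsAsFactors = FALSE))
  cohort_table(long)
}

subset_cohort <- function(table, group = NULL, region = NULL, range = NULL) {
  sel <- rep(TRUE, nrow(table))
  if (!is.null(group)) sel <- sel & table$group == group
  if (!is.null(region)) sel <- sel & table$region == region
  if (!is.null(range)) sel <- sel & abs(table$range - range) < 1e-9
  as.data.frame(table[sel, , drop = FALSE])
}

#' One-way ANOVA with Tukey post-hoc across regions
#'
#' Tests whether the stiffness metric differs among the three tested regions
#' (LV, RV, OFT) within one genotype group and strain range, then adjusts the
#' three pairwise comparisons with Tukey's honest significant difference
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param table A [cohort_table].
#' @param group Genotype group to test within (default `"control"`).
#' @param range Strain range tag (0.2 or 0.4).
#' @return A list with `F`, `p`, `df`, and a `tukey` data frame of pairwise
#'   differences and adjusted p-values.
#' @export
anova_tukey <- function(table, group = "control", range = 0.4) {
  d <- subset_cohort(table, group = group, range = range)
  counts <- table(d$region)
  if (length(counts) < 2L || any(counts < 2L))
    pa_stop("each region needs at least 2 observations for ANOVA",
            "pamech_degenerate_design")
  d$region <- factor(d$region)
  if (var(d$value) <= 1e-300) {
    pairs <- utils::combn(levels(d$region), 2,
                          function(p) paste(p[2L], p[1L], sep = "-"))
    return(list(F = 0, p = 1, df = c(length(counts) - 1L, nrow(d) - length(counts)),
                tukey = data.frame(pair = pairs, diff = 0, p_adj = 1,
                                   stringsAsFactors = FALSE)))
  }
  fit <- aov(value ~ region, data = d)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$region
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       df = an[["Df"]],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Two-sample genotype t-test
#'
#' Compares the stiffness metric between control and mutant cohorts at one
#' region and strain range.  Defaults to the pooled-variance (Student) form;
#' set `var_equal = FALSE` for Welch.
#'
#' @param table A [cohort_table].
#' @param region Region label.
#' @param range Strain range tag.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A list with `t`, `p`, `df`, and the two group means.
#' @export
genotype_ttest <- function(table, region = "RV", range = 0.4,
                           var_equal = TRUE) {
  d <- subset_cohort(table, region = region, range = range)
  groups <- unique(d$group)
  if (!all(c("control", "mutant") %in% groups))
    pa_stop("both control and mutant groups must be present",
            "pamech_degenerate_design")
  x <- d$value[d$group == "control"]
  y <- d$value[d$group == "mutant"]
  m <- c(control = mean(x), mutant = mean(y))
  if (sd(x) <= 1e-300 && sd(y) <= 1e-300) {
    # zero variance in both groups: p = 1 by convention when means agree
    if (abs(m[1L] - m[2L]) <= 1e-300)
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2L, means = m))
    return(list(t = Inf, p = 0, df = length(x) + length(y) - 2L, means = m))
  }
  tt <- t.test(y, x, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       means = m)
}

#' Mutant-to-control stiffness ratio
#'
#' Ratio of the mutant group mean to the control group mean of the stiffness
#' metric at one region and range, reported to 2 significant figures.
#'
#' @param table A [cohort_table], or a numeric vector of length 2
#'   `(control_mean, mutant_mean)`.
#' @param region,range Selection when `table` is a cohort table.
#' @param digits Significant figures for the reported ratio.
#' @return The (rounded) ratio, dimensionless.
#' @export
stiffness_ratio <- function(table, region = "RV", range = 0.4, digits = 2) {
  if (is.numeric(table) && length(table) == 2L) {
    ctrl <- table[1L]
    mut <- table[2L]
  } else {
    d <- subset_cohort(table, region = region, range = range)
    ctrl <- mean(d$value[d$group == "control"])
    mut <- mean(d$value[d$group == "mutant"])
  }
  if (!is.finite(ctrl) || ctrl <= 0)
    pa_stop("control mean must be positive for a stiffness ratio",
            "pamech_undefined_ratio")
  signif(mut / ctrl, digits)
}

#' Full cohort statistics report
#'
#' Convenience wrapper reproducing the standard comparison set from a SED
#' table: per-group/range region ANOVA with Tukey pairs, and per-region/range
#' genotype t-tests with mutant/control ratios.
#'
#' @param summary_df Output of [sed_table()].
#' @param out Optional CSV path for the combined report.
#' @return A `data.frame` report.
#' @export
stats_report <- function(summary_df, out = NULL) {
  tab <- as_cohort_table(summary_df)
  rows <- list()
  for (rg in intersect(c(0.2, 0.4), unique(tab$range))) {
    for (g in intersect(c("control", "mutant"), unique(tab$group))) {
      ok <- tryCatch({
        a <- anova_tukey(tab, group = g, range = rg)
        rows[[length(rows) + 1L]] <- data.frame(
          test = "anova", group = g, region = paste(a$tukey$pair, collapse = ";"),
          range = rg, statistic = a$F, p = a$p,
          detail = paste(sprintf("%s:p=%.4g", a$tukey$pair, a$tukey$p_adj),
                         collapse = ";"),
          stringsAsFactors = FALSE)
        TRUE
      }, pamech_error = function(e) FALSE)
    }
    for (rgn in unique(tab$region)) {
      ok <- tryCatch({
        tt <- genotype_ttest(tab, region = rgn, range = rg)
        rt <- stiffness_ratio(tab, region = rgn, range = rg)
        rows[[length(rows) + 1L]] <- data.frame(
          test = "ttest", group = "mutant-vs-control", region = rgn, range = rg,
          statistic = tt$t, p = tt$p,
          detail = sprintf("ratio=%.3g", rt), stringsAsFactors = FALSE)
        TRUE
      }, pamech_error = function(e) FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  if (!is.null(out)) write.csv(rep, out, row.names = FALSE)
  rep
}
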