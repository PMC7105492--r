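#' Two-sample Student's t-test with group summaries
#'
#' Pooled-variance Student's t by default (Welch selectable); one-sided only
#' when a direction is declared, mirroring the policy of testing one-sided
#' when a change direction is expected and two-sided otherwise.
#'
#' @param group_a,group_b numeric vectors (one value per animal).
#' @param alternative "two.sided", "less", or "greater" (A relative to B).
#' @param var_equal pooled variance (classic Student's t) when TRUE.
#' @return list with `mean_a`, `sem_a`, `mean_b`, `sem_b`, `t`, `df`, `p`,
#'   `alternative`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(group_a, group_b, alternative = "two.sided",
                         var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      stop("zero variance in both groups")
  }
  tt <- stats::t.test(group_a, group_b, alternative = alternative,
                      var.equal = var_equal)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(mean_a = mean(group_a), sem_a = sem(group_a),
       mean_b = mean(group_b), sem_b = sem(group_b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alternative = alternative,
       n_a = length(group_a), n_b = length(group_b))
}

#' Repeated-measures two-way ANOVA with partial eta squared
#'
#' Group (between subjects) by radius (within subjects) ANOVA with
#' sphericity assumed, the design used for Sholl profiles (subjects =
#' animals, one profile per animal). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error
#' stratum. Unbalanced designs are rejected.
#'
#' @param data data frame with columns `subject`, `group`, `radius`,
#'   `value`.
#' @return data frame with rows `group`, `radius`, `group:radius` and
#'   columns `df1`, `df2`, `F`, `p`, `partial_eta_sq`.
#' @export
rm_two_way_anova <- function(data) {
  stopifnot(all(c("subject", "group", "radius", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$radius <- factor(data$radius)
  tab <- table(data$subject, data$radius)
  if (length(unique(tab[tab > 0])) != 1 || any(tab == 0) ||
      length(unique(table(data$group) / nlevels(data$radius))) != 1)
    stop("unbalanced design: every animal needs every radius, equal group sizes")
  fit <- stats::aov(value ~ group * radius + Error(subject / radius),
                    data = data)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: subject:radius"]][[1]]
  pick <- function(stratum, term) {
    i <- match(term, trimws(rownames(stratum)))
    e <- match("Residuals", trimws(rownames(stratum)))
    data.frame(effect = term, df1 = stratum$Df[i], df2 = stratum$Df[e],
               F = stratum$`F value`[i], p = stratum$`Pr(>F)`[i],
               partial_eta_sq = stratum$`Sum Sq`[i] /
                 (stratum$`Sum Sq`[i] + stratum$`Sum Sq`[e]))
  }
  out <- rbind(pick(between, "group"),
               pick(within, "radius"),
               pick(within, "group:radius"))
  rownames(out) <- NULL
  out
}

#' Normality screen
#'
#' Shapiro-Wilk per group, reported alongside parametric tests (never used
#' to auto-switch tests).
#'
#' @param x numeric vector.
#' @return p-value (NA when n < 3 or the values are constant).
#' @export
normality_p <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' Western-blot band normalization
#'
#' Per lane: intensity divided by the run-calibrator lane of the same blot
#' (both for the target protein and for actin), then the actin-corrected
#' ratio, then division by the control-group mean so the control group
#' averages exactly 1.0. Invariant under per-blot multiplicative gain and
#' under global actin rescaling.
#'
#' @param bands data frame with columns `blot`, `sample`, `group`
#'   (`"control"`/`"cr"` or any two labels with control first in factor
#'   order), `protein`, `actin`, `is_calibrator` (logical; exactly one per
#'   blot).
#' @param control_label group label defining the reference mean.
#' @return `bands` with columns `calibrated`, `actin_ratio`, `normalized`
#'   added; attribute `group_means`.
#' @export
wb_normalize <- function(bands, control_label = "control") {
  need <- c("blot", "sample", "group", "protein", "actin", "is_calibrator")
  stopifnot(all(need %in% names(bands)))
  out <- do.call(rbind, lapply(split(bands, bands$blot), function(b) {
    cal <- which(b$is_calibrator)
    if (length(cal) != 1)
      stop("each blot needs exactly one calibrator lane (blot ",
           b$blot[1], ")")
    if (any(!is.finite(b$actin)) || any(b$actin <= 0))
      stop("missing or non-positive actin lane (blot ", b$blot[1], ")")
    b$calibrated <- b$protein / b$protein[cal]
    b$actin_cal <- b$actin / b$actin[cal]
    b$actin_ratio <- b$calibrated / b$actin_cal
    b
  }))
  rownames(out) <- NULL
  ctrl <- out$group == control_label & !out$is_calibrator
  if (!any(ctrl)) stop("no control-group lanes")
  out$normalized <- out$actin_ratio / mean(out$actin_ratio[ctrl])
  keep <- !out$is_calibrator
  gm <- tapply(out$normalized[keep], out$group[keep], mean)
  attr(out, "group_means") <- gm
  out
}
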