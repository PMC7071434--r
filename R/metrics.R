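#' Pearson correlation coefficient
#'
#' @param x,y Equal-length numeric vectors, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300)
    stop("correlation of a constant signal is undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Root-mean-square error
#'
#' @param x,y Equal-length numeric vectors (microvolts in this package's
#'   pipelines).
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Coefficient of determination about the reference mean
#'
#' `1 - SS_res / SS_tot` with residuals `ref - pred` and total sum of squares
#' about the mean of `ref`.  Can be negative when the prediction is worse
#' than the reference mean.
#'
#' @param ref Reference signal.
#' @param pred Reconstructed signal.
#' @return R-squared (<= 1).
#' @export
r_square <- function(ref, pred) {
  if (length(ref) == 0L) stop("empty input", call. = FALSE)
  if (length(ref) != length(pred))
    stop("`ref` and `pred` must have equal length", call. = FALSE)
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot < 1e-300)
    stop("reference signal is constant; R-squared undefined", call. = FALSE)
  1 - sum((ref - pred)^2) / ss_tot
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, from the
#' ANOVA mean squares of the targets-by-raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings n x k numeric matrix: n targets (e.g. time samples or
#'   subjects) rated by k raters (e.g. reference and reconstruction).
#' @return ICC(2,1).
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("need at least 2 targets and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean paired difference), limits of agreement (bias +/- 1.96 SD of
#' the differences) and the slope of difference on mean (proportional-error
#' check).  Units follow the inputs; the study design reports limits in mV.
#'
#' @param ref,pred Equal-length numeric vectors.
#' @return List of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, `slope`, `n`.
#' @export
bland_altman <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) < 3L)
    stop("need equal-length inputs with at least 3 points", call. = FALSE)
  d <- pred - ref
  m <- (pred + ref) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- if (stats::sd(m) < 1e-300) NA_real_
           else unname(stats::coef(stats::lm(d ~ m))[2L])
  structure(list(bias = bias, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s, sd_diff = s,
                 slope = slope, n = length(d)),
            class = "bland_altman")
}

#' Paired comparison of two shape families (Wilcoxon signed rank)
#'
#' Two-sided signed-rank test on paired scores — one pair per (subject, lead)
#' at each family's selected combination.  The exact distribution is used for
#' n <= 25 pairs without ties; otherwise the normal approximation with
#' continuity correction (the `stats::wilcox.test` conventions).
#'
#' @param scores_a,scores_b Equal-length paired score vectors.
#' @return List: `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n`.
#' @export
compare_shapes <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired scores must have equal length", call. = FALSE)
  d <- scores_a - scores_b
  if (all(d == 0))
    stop("all paired differences are zero; signed-rank test degenerate",
         call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                       exact = length(d) <= 25 && !any(d == 0) &&
                         !anyDuplicated(abs(d[d != 0])),
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = sum(d != 0))
}

#' Per-lead one-way ANOVA across electrode positions
#'
#' For each lead, a one-way fixed-effects ANOVA of per-subject CCs across the
#' position groups (e.g. a base combination and its one-step shifts).
#'
#' @param score_table Data frame with columns `lead`, `position` (factor or
#'   character, >= 2 levels) and `score` (>= 2 replicates per group).
#' @return Data frame with one row per lead: `lead`, `f_value`, `p_value`,
#'   `df_between`, `df_within`.
#' @export
compare_orientations <- function(score_table) {
  stopifnot(all(c("lead", "position", "score") %in% names(score_table)))
  out <- lapply(split(score_table, score_table$lead), function(d) {
    d$position <- factor(d$position)
    if (nlevels(d$position) < 2L || any(table(d$position) < 2L))
      stop("each lead needs >= 2 positions with >= 2 replicates",
           call. = FALSE)
    av <- stats::anova(stats::aov(score ~ position, data = d))
    data.frame(lead = d$lead[1L], f_value = av$`F value`[1L],
               p_value = av$`Pr(>F)`[1L], df_between = av$Df[1L],
               df_within = av$Df[2L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
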