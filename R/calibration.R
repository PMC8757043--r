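#' Default alpha sweep grid
#'
#' The grid used by the calibration sweep: dense around 0 where the
#' threshold crosses the median, coarser toward the saturating extremes.
#'
#' @return Numeric vector of 15 alpha values.
#' @export
default_alpha_grid <- function() {
  c(-3, -2, -1, -0.75, -0.5, -0.25, -0.1, 0, 0.1, 0.25, 0.5, 0.75, 1, 2, 3)
}

#' Alarm-count histogram over a cohort
#'
#' Counts how many cases landed in each risk-score category 0..`max_alarms`
#' (the maximum is n_sources x n_metrics under class-mean reduction).
#'
#' @param report an `alarm_report` from [raise_alarms()], or a vector of
#'   risk scores.
#' @param max_alarms top category (inclusive).
#' @return Integer vector of length `max_alarms + 1`, named "0".."max".
#' @export
alarm_histogram <- function(report, max_alarms) {
  risk <- if (inherits(report, "alarm_report")) report$summary$risk_score
          else as.integer(report)
  if (any(risk > max_alarms))
    stop("risk score exceeds `max_alarms`")
  counts <- tabulate(risk + 1L, nbins = max_alarms + 1L)
  names(counts) <- as.character(0:max_alarms)
  counts
}

#' Shannon entropy of an alarm-count histogram (nats)
#'
#' `H = -sum p_k log p_k` over non-empty categories, natural logarithm.
#' A flat histogram (risk scores spread evenly over the cohort) maximizes
#' entropy at `log(K)`; a saturated one (all cases in one bin) gives 0.
#' High entropy means the risk score actually discriminates cases, which is
#' why entropy is one of the calibration objectives for alpha.
#'
#' @param counts non-negative category counts, summing to > 0.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("all-zero histogram")
  p <- counts[counts > 0] / total
  -sum(p * log(p)) + 0  # + 0 turns IEEE -0 (one-bin case) into +0
}

#' Pearson correlation with guarded degenerate cases
#'
#' Standard product-moment correlation after dropping pairs whose `y` is
#' `NaN` or infinite (infinite Hausdorff values, from empty masks, carry no
#' usable magnitude). Returns `NA` when fewer than 3 valid pairs remain or
#' when either series is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(y) & !is.na(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Sweep alpha and characterize the alarm distribution
#'
#' For each alpha in the grid: recompute thresholds and alarms from the
#' metric table, histogram the risk scores, and take the histogram's
#' Shannon entropy. When reference quality is supplied, also correlate
#' risk scores with the fused mask's ground-truth Dice (`r_dice`) and
#' Hausdorff (`r_hd`) per case — a good alpha yields strongly negative
#' `r_dice` (more alarms on worse cases).
#'
#' @param table a [metric_table()].
#' @param gt_quality optional data.frame from [fusion_gt_quality()]
#'   (columns case_id, gt_dice, gt_hd).
#' @param alphas numeric grid, default [default_alpha_grid()].
#' @return data.frame with one row per alpha: alpha, entropy, r_dice, r_hd,
#'   then one `a<k>` column per alarm-count category.
#' @export
sweep_alpha <- function(table, gt_quality = NULL,
                        alphas = default_alpha_grid()) {
  vals <- metric_values(table)
  n_classes <- if (is.null(table$reduced)) length(table$class_names) else 1L
  max_alarms <- length(table$roster) * length(table$metrics) * n_classes
  rows <- lapply(sort(alphas), function(a) {
    rep_ <- raise_alarms(table, alarm_thresholds(table, alpha_config(a)))
    h <- alarm_histogram(rep_, max_alarms)
    r_dice <- r_hd <- NA_real_
    if (!is.null(gt_quality)) {
      m <- merge(rep_$summary, gt_quality, by = "case_id")
      r_dice <- pearson_r(m$risk_score, m$gt_dice)
      r_hd <- pearson_r(m$risk_score, m$gt_hd)
    }
    out <- data.frame(alpha = a, entropy = shannon_entropy(h),
                      r_dice = r_dice, r_hd = r_hd)
    out[paste0("a", names(h))] <- as.list(unname(h))
    out
  })
  do.call(rbind, rows)
}

#' Recommend an alpha from a calibration sweep
#'
#' Argmax of the chosen objective over the sweep rows:
#' `max_abs_r_dice` picks the alpha whose risk scores track reference Dice
#' most strongly (|r_dice|); `max_entropy` picks the most discriminative
#' alarm distribution; `combined` rank-sums both (higher rank = better on
#' each axis). Ties resolve toward the smaller alpha — the more sensitive,
#' conservative choice.
#'
#' @param rows data.frame from [sweep_alpha()].
#' @param objective `"max_abs_r_dice"`, `"max_entropy"`, or `"combined"`.
#' @return The recommended alpha (one element of `rows$alpha`).
#' @export
recommend_alpha <- function(rows,
                            objective = c("max_abs_r_dice", "max_entropy",
                                          "combined")) {
  objective <- match.arg(objective)
  score <- switch(objective,
    max_abs_r_dice = abs(rows$r_dice),
    max_entropy = rows$entropy,
    combined = rank(abs(rows$r_dice), na.last = FALSE) +
               rank(rows$entropy, na.last = FALSE))
  if (all(is.na(score))) stop("objective is NA for every row")
  best <- which(score == max(score, na.rm = TRUE))
  rows$alpha[best][which.min(rows$alpha[best])]
}

#' Write a calibration sweep as CSV
#'
#' Columns alpha, entropy, r_dice, r_hd, then one column per alarm-count
#' category.
#'
#' @param rows data.frame from [sweep_alpha()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
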