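#' Alpha (sensitivity) configuration
#'
#' One alarm threshold is derived per (algorithm, class, metric) series as
#' median - MAD * alpha, so alpha tunes sensitivity: at alpha = 0 the
#' threshold sits at the median (about half the cases alarm per metric);
#' larger alpha flags only stronger outliers. Alpha is addressable per
#' (source_id, class_name, metric) with a global fallback — e.g. a
#' clinically critical class can be given a smaller alpha than the rest.
#'
#' @param default global alpha (default 0.1).
#' @param overrides optional data.frame with columns `source_id`,
#'   `class_name`, `metric`, `alpha`; `NA` in a key column is a wildcard.
#'   The most specific matching row (most non-wildcard keys) wins; first
#'   row wins specificity ties.
#' @return An object of class `alpha_config`.
#' @export
alpha_config <- function(default = 0.1, overrides = NULL) {
  if (!is.null(overrides)) {
    need <- c("source_id", "class_name", "metric", "alpha")
    if (!all(need %in% names(overrides)))
      stop("`overrides` must have columns ", paste(need, collapse = ", "))
  }
  structure(list(default = as.numeric(default), overrides = overrides),
            class = "alpha_config")
}

resolve_alpha <- function(config, source_id, class_name, metric) {
  if (is.numeric(config)) return(as.numeric(config))
  ov <- config$overrides
  if (is.null(ov) || nrow(ov) == 0L) return(config$default)
  keymatch <- function(key, val)
    is.na(key) | (!is.na(val) & key == val)
  hits <- keymatch(ov$source_id, source_id) &
    keymatch(ov$class_name, class_name) &
    keymatch(ov$metric, metric)
  if (!any(hits)) return(config$default)
  spec <- rowSums(!is.na(ov[hits, c("source_id", "class_name", "metric")]))
  ov$alpha[hits][which.max(spec)]
}

#' Robust alarm threshold for one metric series
#'
#' threshold = median - MAD * alpha, where MAD is the *unscaled* median
#' absolute deviation from the median (no 1.4826 normal-consistency factor
#' — alpha absorbs any scaling). Median statistics are used for robustness
#' to the very outliers the method is hunting. Non-finite values (`Inf`,
#' `NaN`) are excluded from the estimation — a single empty prediction must
#' not poison the threshold — but such cells always alarm downstream.
#'
#' @param values numeric vector (the oriented metric series over cases).
#' @param alpha sensitivity parameter.
#' @return list with `threshold`, `median`, `mad`, and `n_finite`.
#' @export
robust_threshold <- function(values, alpha) {
  finite <- values[is.finite(values)]
  if (length(finite) < 2L)
    stop("degenerate cohort: need >= 2 finite values to derive a threshold")
  med <- stats::median(finite)
  mad_ <- stats::median(abs(finite - med))
  list(threshold = med - mad_ * alpha, median = med, mad = mad_,
       n_finite = length(finite))
}

#' Orient metric values so "larger is better" uniformly
#'
#' Thresholding assumes higher values mean better agreement. Metrics that
#' are negatively correlated with performance (Hausdorff distance) are
#' mapped to their additive inverse, so `+Inf` becomes `-Inf`; `NaN` passes
#' through. Dice passes through unchanged.
#'
#' @param values numeric vector.
#' @param metric `"dice"` or `"hausdorff"`.
#' @return Oriented numeric vector.
#' @export
orient_values <- function(values, metric) {
  if (metric_orientation(metric) == "lower_better") -values else values
}

#' Derive the threshold table from a metric table
#'
#' For each (source_id, class, metric) series across the cohort's cases
#' (the class axis collapses when the table is class-mean reduced), orients
#' the values, drops non-finite cells, and applies [robust_threshold()].
#' One threshold per algorithm and metric is the intended granularity: a
#' systematically weaker algorithm gets a forgiving threshold instead of
#' alarming everywhere.
#'
#' @param table a [metric_table()].
#' @param alpha an [alpha_config()] or a single number.
#' @return An object of class `threshold_table`: data.frame with columns
#'   source_id, class_name (`NA` when reduced), metric, alpha, median, mad,
#'   threshold (all on the oriented scale).
#' @export
alarm_thresholds <- function(table, alpha = alpha_config()) {
  vals <- metric_values(table)
  key <- unique(vals[, c("source_id", "class_name", "metric")])
  key <- key[order(key$source_id, key$class_name, key$metric), , drop = FALSE]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sel <- vals$source_id == k$source_id & vals$metric == k$metric &
      (is.na(k$class_name) | vals$class_name %in% k$class_name)
    a <- resolve_alpha(alpha, k$source_id, k$class_name, k$metric)
    rt <- robust_threshold(orient_values(vals$value[sel], k$metric), a)
    data.frame(source_id = k$source_id, class_name = k$class_name,
               metric = k$metric, alpha = a, median = rt$median,
               mad = rt$mad, threshold = rt$threshold,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("threshold_table", "data.frame"))
}

#' Raise alarm flags and accumulate per-case risk scores
#'
#' A cell alarms when its oriented value falls strictly below its
#' threshold (equality does not alarm), or when the value is `NaN` or
#' infinite on the bad side (empty predictions). The per-case risk score is
#' the unweighted count of alarms — the triage key.
#'
#' @param table a [metric_table()].
#' @param thresholds a `threshold_table` from [alarm_thresholds()]; must
#'   cover every (source, class, metric) cell of `table`.
#' @return An object of class `alarm_report`: list with `flags` (data.frame
#'   case_id, source_id, class_name, metric, value, threshold, flag) and
#'   `summary` (data.frame case_id, risk_score, plus one `<metric>_flags`
#'   subtotal column per metric).
#' @export
raise_alarms <- function(table, thresholds) {
  vals <- metric_values(table)
  thr_key <- paste(thresholds$source_id, thresholds$class_name,
                   thresholds$metric, sep = "\r")
  val_key <- paste(vals$source_id, vals$class_name, vals$metric, sep = "\r")
  idx <- match(val_key, thr_key)
  if (anyNA(idx))
    stop("threshold table does not cover every metric-table cell")
  oriented <- vals$value
  for (m in unique(vals$metric)) {
    sel <- vals$metric == m
    oriented[sel] <- orient_values(vals$value[sel], m)
  }
  thr <- thresholds$threshold[idx]
  flag <- is.nan(oriented) | oriented == -Inf | (is.finite(oriented) & oriented < thr)
  flags <- data.frame(vals[, c("case_id", "source_id", "class_name", "metric")],
                      value = vals$value, threshold = thr, flag = flag,
                      stringsAsFactors = FALSE)
  case_ids <- sort(unique(vals$case_id))
  summary <- data.frame(case_id = case_ids, stringsAsFactors = FALSE)
  summary$risk_score <- vapply(case_ids, function(cid)
    sum(flags$flag[flags$case_id == cid]), 0L)
  for (m in unique(vals$metric))
    summary[[paste0(m, "_flags")]] <- vapply(case_ids, function(cid)
      sum(flags$flag[flags$case_id == cid & flags$metric == m]), 0L)
  structure(list(flags = flags, summary = summary), class = "alarm_report")
}

#' @export
print.alarm_report <- function(x, ...) {
  cat(sprintf("<alarm_report> %d cases, %d flags raised of %d cells\n",
              nrow(x$summary), sum(x$flags$flag), nrow(x$flags)))
  invisible(x)
}

#' Rank cases for expert review
#'
#' Orders cases by descending risk score — the triage queue: the most
#' failure-prone segmentations first. Ties break by case_id lexicographic
#' order so the ranking is stable and reproducible.
#'
#' @param report an [raise_alarms()] `alarm_report`.
#' @return The summary data.frame, ordered, with a `rank` column prepended.
#' @export
rank_cases <- function(report) {
  s <- report$summary
  s <- s[order(-s$risk_score, s$case_id), , drop = FALSE]
  rownames(s) <- NULL
  cbind(rank = seq_len(nrow(s)), s)
}

#' Write a threshold table as CSV
#'
#' One row per algorithm with one column per metric, de-oriented back to
#' each metric's native scale (so Hausdorff thresholds print positive, as
#' users expect). Per-class tables add a class column.
#'
#' @param thresholds a `threshold_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_threshold_table <- function(thresholds, path) {
  t <- as.data.frame(thresholds)
  t$native <- ifelse(vapply(t$metric, metric_orientation, "") == "lower_better",
                     -t$threshold, t$threshold)
  keys <- if (all(is.na(t$class_name))) "source_id" else c("source_id", "class_name")
  wide <- stats::reshape(t[, c(keys, "metric", "native")],
                         idvar = keys, timevar = "metric", direction = "wide")
  names(wide) <- sub("^native\\.", "", names(wide))
  names(wide)[names(wide) == "source_id"] <- "algorithm"
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an alarm report as CSV
#'
#' @param report an `alarm_report`.
#' @param flags_path CSV of per-cell flags; `NULL` to skip.
#' @param summary_path CSV of per-case risk scores; `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_alarm_report <- function(report, flags_path = NULL, summary_path = NULL) {
  if (!is.null(flags_path)) {
    f <- report$flags
    f$value <- format_metric_value(f$value)
    utils::write.csv(f, flags_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path))
    utils::write.csv(report$summary, summary_path, row.names = FALSE, quote = FALSE)
  invisible(report)
}
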