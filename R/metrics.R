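#' Volumetric Dice coefficient
#'
#' `2|A∩B| / (|A|+|B|)` over foreground voxels; spacing-independent by
#' definition. Both masks empty gives `NaN` — unanimity on "nothing there"
#' carries no overlap information and is deliberately not scored as perfect
#' (downstream, `NaN` raises an alarm so such cases reach a human). Exactly
#' one empty mask gives 0.
#'
#' @param a,b binary [seg_mask()] on the same grid.
#' @return Numeric in `[0, 1]`, or `NaN`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  sa <- sum(a$voxels); sb <- sum(b$voxels)
  if (sa == 0L && sb == 0L) return(NaN)
  if (sa == 0L || sb == 0L) return(0.0)
  2 * sum(a$voxels & b$voxels) / (sa + sb)
}

fg_coords <- function(mask) {
  w <- which(mask$voxels != 0L, arr.ind = TRUE)
  storage.mode(w) <- "double"
  w
}

#' Hausdorff distance in mm
#'
#' Classic (100th-percentile) symmetric Hausdorff distance between the two
#' foreground voxel sets: the larger of the two directed
#' farthest-nearest-point distances, with voxel index offsets scaled by the
#' anisotropic spacing so the result is in mm. Exactly one empty mask gives
#' `+Inf` (there is no nearest point); both empty gives `NaN`. A percentile
#' variant (e.g. HD95) is available via `percentile` but is not used by the
#' pipeline defaults.
#'
#' @param a,b binary [seg_mask()] on the same grid (shape and spacing).
#' @param percentile percentile of the directed nearest-neighbour distance
#'   distributions, in (0, 100]; 100 (default) is the classic maximum.
#' @return Non-negative distance in mm, `+Inf`, or `NaN`.
#' @export
hausdorff <- function(a, b, percentile = 100) {
  stop_if_grid_mismatch(a, b)
  ca <- fg_coords(a); cb <- fg_coords(b)
  if (nrow(ca) == 0L && nrow(cb) == 0L) return(NaN)
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(Inf)
  if (percentile >= 100)
    return(cpp_hausdorff_max(ca, cb, a$spacing))
  d_ab <- cpp_min_dists(ca, cb, a$spacing)
  d_ba <- cpp_min_dists(cb, ca, a$spacing)
  max(stats::quantile(d_ab, percentile / 100, names = FALSE),
      stats::quantile(d_ba, percentile / 100, names = FALSE))
}

metric_orientation <- function(metric) {
  switch(metric,
         dice = "higher_better",
         hausdorff = "lower_better",
         stop("unknown metric: ", metric))
}

compute_metric <- function(metric, a, b) {
  switch(metric,
         dice = dice(a, b),
         hausdorff = hausdorff(a, b),
         stop("unknown metric: ", metric))
}

# Class-mean with the propagation rules used throughout: any infinite
# member dominates (Inf), otherwise any NaN member poisons (NaN).
reduce_mean <- function(x) {
  if (any(is.infinite(x))) return(Inf)
  if (any(is.nan(x))) return(NaN)
  mean(x)
}

#' Candidate-vs-fusion metric table for a cohort
#'
#' For every (case, source, class, metric) cell, binarizes the fused mask
#' and the candidate to the class and evaluates the metric — the similarity
#' grid that thresholds and alarms are derived from. With
#' `class_reduce = "mean"` an additional reduced table averages over classes
#' per (case, source, metric) so each (source, metric) contributes one alarm
#' opportunity per case; the class mean propagates `Inf` (any infinite
#' member) then `NaN` (any undefined member).
#'
#' @param cohort list of [case_ensemble()].
#' @param fusions named list of fused [seg_mask()] keyed by case_id
#'   (see [fuse_cohort()]).
#' @param spec a [class_spec()].
#' @param metrics character vector from `"dice"`, `"hausdorff"`.
#' @param class_reduce `"mean"` (default) or `"none"`.
#' @return An object of class `metric_table`: list with `cells` (data.frame
#'   case_id, source_id, class_name, metric, value), `reduced` (data.frame
#'   case_id, source_id, metric, value, or `NULL`), and the roster/class/
#'   metric bookkeeping.
#' @export
metric_table <- function(cohort, fusions, spec,
                         metrics = c("dice", "hausdorff"),
                         class_reduce = c("mean", "none")) {
  class_reduce <- match.arg(class_reduce)
  metrics <- match.arg(metrics, several.ok = TRUE)
  case_ids <- vapply(cohort, function(e) e$case_id, "")
  missing_f <- setdiff(case_ids, names(fusions))
  if (length(missing_f))
    stop("missing fusion for case(s): ", paste(missing_f, collapse = ", "))
  roster <- sort(names(cohort[[1]]$candidates))
  rows <- list(); i <- 0L
  for (ens in cohort) {
    if (!setequal(names(ens$candidates), roster))
      stop("source roster mismatch in case '", ens$case_id, "'")
    fus <- fusions[[ens$case_id]]
    fus_bin <- lapply(spec$class_ids, function(ids) binarize(fus, ids))
    for (src in roster) {
      cand <- ens$candidates[[src]]
      for (k in seq_along(spec$class_ids)) {
        cand_bin <- binarize(cand, spec$class_ids[[k]])
        for (m in metrics) {
          i <- i + 1L
          rows[[i]] <- data.frame(
            case_id = ens$case_id, source_id = src,
            class_name = spec$class_names[k], metric = m,
            value = compute_metric(m, fus_bin[[k]], cand_bin),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  reduced <- NULL
  if (class_reduce == "mean") {
    agg <- stats::aggregate(value ~ case_id + source_id + metric, data = cells,
                            FUN = reduce_mean, na.action = stats::na.pass)
    reduced <- agg[order(agg$case_id, agg$source_id, agg$metric), , drop = FALSE]
    rownames(reduced) <- NULL
  }
  structure(list(cells = cells, reduced = reduced, roster = roster,
                 class_names = spec$class_names, metrics = metrics,
                 class_reduce = class_reduce),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %d cases x %d sources x %d classes x %d metrics (%s)\n",
              length(unique(x$cells$case_id)), length(x$roster),
              length(x$class_names), length(x$metrics),
              if (is.null(x$reduced)) "unreduced" else "class-mean reduced"))
  invisible(x)
}

# The alarm-bearing view: class-mean rows when reduction is on, otherwise
# the full per-class grid (with class_name kept as a threshold dimension).
metric_values <- function(table) {
  if (!is.null(table$reduced)) {
    out <- table$reduced
    out$class_name <- NA_character_
    out[, c("case_id", "source_id", "class_name", "metric", "value")]
  } else {
    table$cells
  }
}

format_metric_value <- function(v) {
  ifelse(is.nan(v), "nan", ifelse(is.infinite(v), "inf", format(v, digits = 10)))
}

#' Write a metric table as tidy CSV
#'
#' Columns case_id, source_id, class_name, metric, value with `Inf`/`NaN`
#' spelled `"inf"`/`"nan"`. The class-mean reduced table, when present, is
#' appended with class_name `"(mean)"`.
#'
#' @param table a [metric_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  df <- table$cells
  if (!is.null(table$reduced)) {
    red <- table$reduced
    red$class_name <- "(mean)"
    df <- rbind(df, red[, names(df)])
  }
  df$value <- format_metric_value(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fusion-vs-ground-truth quality per case
#'
#' Reference quality of each case's fused mask: class-mean Dice and
#' class-mean Hausdorff against the ground truth (class means propagate
#' `Inf` then `NaN`). This is the validation axis that risk scores are
#' correlated against during calibration.
#'
#' @param cohort list of [case_ensemble()] carrying ground truth.
#' @param fusions named list of fused masks keyed by case_id.
#' @param spec a [class_spec()].
#' @return data.frame with columns case_id, gt_dice, gt_hd.
#' @export
fusion_gt_quality <- function(cohort, fusions, spec) {
  rows <- lapply(cohort, function(ens) {
    if (is.null(ens$ground_truth))
      stop("case '", ens$case_id, "' has no ground truth")
    fus <- fusions[[ens$case_id]]
    d <- h <- numeric(length(spec$class_ids))
    for (k in seq_along(spec$class_ids)) {
      fb <- binarize(fus, spec$class_ids[[k]])
      gb <- binarize(ens$ground_truth, spec$class_ids[[k]])
      d[k] <- dice(fb, gb)
      h[k] <- hausdorff(fb, gb)
    }
    data.frame(case_id = ens$case_id, gt_dice = reduce_mean(d),
               gt_hd = reduce_mean(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
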