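#' Fusion configuration
#'
#' Settings for consensus building. `majority` is equal-weight majority
#' voting; `simple` is SIMPLE (Selective and Iterative Method for
#' Performance Level Estimation): iterative weighted voting that estimates
#' each candidate's performance against the current consensus and discards
#' poor performers.
#'
#' @param method `"majority"` or `"simple"`.
#' @param simple_max_iters iteration cap for SIMPLE (>= 1).
#' @param simple_discard_sd a retained candidate is discarded when its
#'   estimated performance falls below mean - `simple_discard_sd` * sd of
#'   the retained performances. The default 1 is chosen so that a clear
#'   outlier in a small ensemble is actually removable: for a sample of n
#'   values the largest deviation from the mean is at most
#'   `sd * (n-1)/sqrt(n)`, so a factor of 2 can discard nothing until
#'   n >= 6 — useless for the 3-5 member ensembles this tool targets.
#' @param tie_rule how an exact 50/50 vote resolves for even ensembles:
#'   `"background"` (default, conservative: an under-segmented fusion
#'   lowers candidate agreement, which errs toward raising alarms) or
#'   `"foreground"`.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(method = c("majority", "simple"),
                          simple_max_iters = 25L,
                          simple_discard_sd = 1.0,
                          tie_rule = c("background", "foreground")) {
  method <- match.arg(method)
  tie_rule <- match.arg(tie_rule)
  simple_max_iters <- as.integer(simple_max_iters)
  if (simple_max_iters < 1L) stop("`simple_max_iters` must be >= 1")
  if (simple_discard_sd < 0) stop("`simple_discard_sd` must be non-negative")
  structure(list(method = method, simple_max_iters = simple_max_iters,
                 simple_discard_sd = simple_discard_sd, tie_rule = tie_rule),
            class = "fusion_config")
}

check_binary <- function(masks) {
  for (m in masks)
    if (any(m$voxels > 1L)) stop("expected binary masks (labels 0/1)")
  invisible(TRUE)
}

check_one_grid <- function(masks) {
  if (length(masks) < 2L) stop("need >= 2 candidates")
  for (m in masks[-1]) stop_if_grid_mismatch(masks[[1]], m)
  invisible(TRUE)
}

#' Equal-weight majority voting over binary masks
#'
#' A voxel is foreground iff strictly more than half of the candidates mark
#' it foreground; an exact tie (possible for even ensembles) resolves per
#' `tie_rule`. Deterministic and invariant to candidate order.
#'
#' @param candidates list of >= 2 binary [seg_mask()] on one grid.
#' @param tie_rule `"background"` (default) or `"foreground"`.
#' @return The fused binary [seg_mask()].
#' @export
majority_vote <- function(candidates, tie_rule = c("background", "foreground")) {
  tie_rule <- match.arg(tie_rule)
  check_one_grid(candidates)
  check_binary(candidates)
  n <- length(candidates)
  votes <- Reduce(`+`, lapply(candidates, function(m) m$voxels))
  fg <- if (tie_rule == "background") votes * 2L > n else votes * 2L >= n
  seg_mask(array(as.integer(fg), dim = dim(votes)),
           spacing = candidates[[1]]$spacing,
           case_id = candidates[[1]]$case_id, source_id = "fusion")
}

#' Majority voting over multi-label maps
#'
#' Per voxel each candidate votes for the evaluation class containing its
#' label (or for background when the label belongs to no class). The class
#' with the most votes wins; background wins any tie it is part of; ties
#' between classes resolve by `precedence` order. The winning class is
#' written as the first label ID of its set.
#'
#' @param candidates list of >= 2 [seg_mask()] on one grid.
#' @param spec a [class_spec()]; class label-ID sets must be disjoint.
#' @param precedence character vector of class names, most preferred first.
#'   Defaults to the order of `spec`.
#' @return The fused multi-label [seg_mask()].
#' @export
majority_vote_multilabel <- function(candidates, spec,
                                     precedence = spec$class_names) {
  check_one_grid(candidates)
  all_ids <- unlist(spec$class_ids)
  if (anyDuplicated(all_ids))
    stop("multi-label voting requires disjoint class label sets")
  if (!setequal(precedence, spec$class_names))
    stop("`precedence` must be a permutation of the class names")
  n <- length(candidates)
  nvox <- prod(dim(candidates[[1]]$voxels))
  ord <- match(precedence, spec$class_names)
  counts <- matrix(0L, nrow = nvox, ncol = length(ord))
  for (m in candidates) {
    v <- as.vector(m$voxels)
    for (k in seq_along(ord))
      counts[, k] <- counts[, k] + (v %in% spec$class_ids[[ord[k]]])
  }
  bg <- n - rowSums(counts)
  # columns already sit in precedence order, so "first" implements the tie rule
  win <- max.col(counts, ties.method = "first")
  best <- counts[cbind(seq_len(nvox), win)]
  reps <- vapply(spec$class_ids[ord], `[`, integer(1), 1L)
  out <- ifelse(best > bg, reps[win], 0L)
  seg_mask(array(as.integer(out), dim = dim(candidates[[1]]$voxels)),
           spacing = candidates[[1]]$spacing,
           case_id = candidates[[1]]$case_id, source_id = "fusion")
}

# Candidate-vs-consensus agreement used inside SIMPLE: Dice, except that
# two empty masks count as perfect agreement (weighting needs a number,
# and an all-empty consensus trivially agrees with an empty candidate).
simple_perf <- function(cand, fusion) {
  d <- dice(cand, fusion)
  if (is.nan(d)) 1.0 else d
}

weighted_vote <- function(candidates, weights, tie_rule) {
  mass <- Reduce(`+`, Map(function(m, w) w * m$voxels, candidates, weights))
  half <- sum(weights) / 2
  fg <- if (tie_rule == "background") mass > half else mass >= half
  seg_mask(array(as.integer(fg), dim = dim(candidates[[1]]$voxels)),
           spacing = candidates[[1]]$spacing,
           case_id = candidates[[1]]$case_id, source_id = "fusion")
}

#' SIMPLE iterative fusion
#'
#' Starts from the equal-weight majority vote, then alternates: (1) estimate
#' each retained candidate's performance as its Dice overlap with the
#' current fusion; (2) discard candidates whose performance falls below
#' mean - `simple_discard_sd` * sd of the retained performances (skipped
#' while two or fewer candidates remain, where the spread estimate is
#' degenerate); (3) re-fuse the retained candidates by performance-weighted
#' voting (foreground iff the weighted foreground mass exceeds half the
#' total retained weight). Stops when the retained set and the fused mask
#' are both unchanged, or after `simple_max_iters` iterations. If every
#' candidate would be discarded, the plain majority vote of all candidates
#' is returned with a warning.
#'
#' @param candidates list of >= 2 binary [seg_mask()] on one grid.
#' @param config a [fusion_config()].
#' @return A list with elements `fusion` (binary [seg_mask()]), `weights`
#'   (named numeric, `NA` for discarded candidates), and `retained`
#'   (character vector of retained candidate names).
#' @export
simple_fuse <- function(candidates, config = fusion_config("simple")) {
  check_one_grid(candidates)
  check_binary(candidates)
  nms <- names(candidates)
  if (is.null(nms)) nms <- paste0("cand", seq_along(candidates))
  names(candidates) <- nms

  fusion <- majority_vote(candidates, tie_rule = config$tie_rule)
  retained <- nms
  for (iter in seq_len(config$simple_max_iters)) {
    perf <- vapply(candidates[retained], simple_perf, 0.0, fusion = fusion)
    keep <- retained
    if (length(retained) > 2L) {
      cut <- mean(perf) - config$simple_discard_sd * stats::sd(perf)
      keep <- retained[perf >= cut]
    }
    if (length(keep) == 0L) {
      warning("SIMPLE discarded every candidate; falling back to majority vote of all")
      w <- rep(NA_real_, length(nms)); names(w) <- nms
      return(list(fusion = majority_vote(candidates, tie_rule = config$tie_rule),
                  weights = w, retained = character(0)))
    }
    w <- perf[keep]
    new_fusion <- weighted_vote(candidates[keep], w, config$tie_rule)
    done <- identical(keep, retained) &&
      identical(new_fusion$voxels, fusion$voxels)
    retained <- keep
    fusion <- new_fusion
    if (done) break
  }
  weights <- rep(NA_real_, length(nms)); names(weights) <- nms
  weights[retained] <- vapply(candidates[retained], simple_perf, 0.0, fusion = fusion)
  list(fusion = fusion, weights = weights, retained = retained)
}

#' Fuse one case's ensemble
#'
#' Dispatches on the configured method and the number of evaluation
#' classes. Multi-label majority voting votes over classes directly; SIMPLE
#' on multi-label input runs per class channel (via [binarize()]) and
#' recomposes the class channels in `precedence` order, highest-precedence
#' class winning overlaps.
#'
#' @param ensemble a [case_ensemble()].
#' @param config a [fusion_config()].
#' @param spec a [class_spec()]; defaults to one class per distinct
#'   non-background label found in the candidates.
#' @param precedence class-name order for multi-label recomposition.
#' @return The fused [seg_mask()]. For SIMPLE, attribute `simple` carries
#'   the per-class weights and retained sets.
#' @export
fuse_case <- function(ensemble, config = fusion_config(), spec = NULL,
                      precedence = NULL) {
  if (is.null(spec)) {
    ids <- sort(unique(unlist(lapply(ensemble$candidates,
                                     function(m) unique(as.vector(m$voxels))))))
    ids <- ids[ids != 0L]
    if (length(ids) == 0L) ids <- 1L
    spec <- class_spec(as.list(ids))
  }
  if (is.null(precedence)) precedence <- spec$class_names
  nc <- length(spec$class_ids)

  if (config$method == "majority") {
    if (nc == 1L) {
      bins <- lapply(ensemble$candidates, binarize, class_ids = spec$class_ids[[1]])
      f <- majority_vote(bins, tie_rule = config$tie_rule)
      f$voxels <- f$voxels * spec$class_ids[[1]][1]
      f$case_id <- ensemble$case_id
      return(f)
    }
    f <- majority_vote_multilabel(ensemble$candidates, spec, precedence)
    f$case_id <- ensemble$case_id
    return(f)
  }

  # SIMPLE, per class channel
  out <- array(0L, dim = mask_shape(ensemble$candidates[[1]]))
  info <- list()
  for (nm in rev(precedence)) {
    k <- match(nm, spec$class_names)
    bins <- lapply(ensemble$candidates, binarize, class_ids = spec$class_ids[[k]])
    res <- simple_fuse(bins, config)
    info[[nm]] <- list(weights = res$weights, retained = res$retained)
    out[res$fusion$voxels == 1L] <- spec$class_ids[[k]][1]
  }
  f <- seg_mask(out, spacing = ensemble$candidates[[1]]$spacing,
                case_id = ensemble$case_id, source_id = "fusion")
  attr(f, "simple") <- info
  f
}

#' Fuse every case in a cohort
#'
#' @param cohort list of [case_ensemble()].
#' @inheritParams fuse_case
#' @return Named list of fused [seg_mask()], keyed by case_id.
#' @export
fuse_cohort <- function(cohort, config = fusion_config(), spec = NULL,
                        precedence = NULL) {
  fusions <- lapply(cohort, fuse_case, config = config, spec = spec,
                    precedence = precedence)
  names(fusions) <- vapply(cohort, function(e) e$case_id, "")
  fusions
}
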