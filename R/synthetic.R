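#' Synthetic cohort configuration
#'
#' Parameters of the phantom-cohort generator used for end-to-end
#' validation. Each case gets a ground-truth phantom of blob components and
#' `n_sources` corrupted candidate masks. Corruption severity is driven by
#' a per-case difficulty grade lambda in `[0, 1]`, shared by all candidates
#' of a case (hard images are hard for every algorithm) plus per-source
#' jitter so the ensemble still disagrees. Candidate error modes mirror the
#' failures seen in real ensembles: boundary over/under-segmentation,
#' missed components, and small spurious components.
#'
#' @param n_cases number of cases in the cohort.
#' @param n_sources ensemble size (candidates per case).
#' @param shape grid dimensions, default `c(64, 64, 64)`.
#' @param spacing voxel spacing in mm.
#' @param classes a [class_spec()]; default one foreground class, label 1.
#' @param n_components range (min, max) of blob components per class.
#' @param comp_radius range of component semi-axes, voxels.
#' @param lambda optional fixed per-case difficulty grades (length
#'   `n_cases`); sampled uniformly on `[0, 1]` when `NULL`.
#' @param lambda_jitter_sd sd of the per-source difficulty jitter.
#' @param p_miss probability a candidate drops a true component, at
#'   lambda = 1 (scaled by lambda).
#' @param p_spurious expected spurious components per candidate at
#'   lambda = 1 (Poisson mean, scaled by lambda).
#' @param boundary_sigma maximum morphological perturbation radius in
#'   voxels, at lambda = 1 (scaled by lambda).
#' @param seed integer; fixing it makes every generated item reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 50L, n_sources = 5L,
                       shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                       classes = class_spec(list(1L), "lesion"),
                       n_components = c(1L, 4L), comp_radius = c(4, 9),
                       lambda = NULL, lambda_jitter_sd = 0.1,
                       p_miss = 0.3, p_spurious = 2, boundary_sigma = 3,
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_sources >= 2, length(shape) == 3, all(shape > 0),
            all(spacing > 0), p_miss >= 0, p_miss <= 1, p_spurious >= 0,
            boundary_sigma >= 0, lambda_jitter_sd >= 0)
  if (!is.null(lambda) && length(lambda) != n_cases)
    stop("`lambda` must have length `n_cases`")
  if (!is.null(lambda) && (any(lambda < 0) || any(lambda > 1)))
    stop("`lambda` grades must lie in [0, 1]")
  structure(list(n_cases = as.integer(n_cases), n_sources = as.integer(n_sources),
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 classes = classes, n_components = as.integer(n_components),
                 comp_radius = as.numeric(comp_radius), lambda = lambda,
                 lambda_jitter_sd = lambda_jitter_sd, p_miss = p_miss,
                 p_spurious = p_spurious, boundary_sigma = boundary_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One RNG stream per generated item: every stochastic step keys its seed on
# (seed, case_index, source_index), so any single mask is reproducible in
# isolation, not just as part of a full cohort run. Kept below 2^31 - 1.
item_seed <- function(seed, case_index, source_index, salt = 0L) {
  (((seed %% 1000003) * 7919 + case_index * 104729 +
      source_index * 1299709 + salt * 15485863) %% 2147483629) + 1
}

coord_grids <- function(shape) {
  z <- array(0L, dim = shape)
  list(x = slice.index(z, 1), y = slice.index(z, 2), z = slice.index(z, 3))
}

ellipsoid_mask <- function(grids, center, semi) {
  ((grids$x - center[1]) / semi[1])^2 +
    ((grids$y - center[2]) / semi[2])^2 +
    ((grids$z - center[3]) / semi[3])^2 <= 1
}

#' Generate one ground-truth phantom
#'
#' Places 1-4 (configurable) random ellipsoidal components per class, away
#' from the volume boundary, mutually separated by at least one voxel so
#' components stay distinct under 6-connectivity and classes never overlap.
#' Deterministic given `(config$seed, case_index)`.
#'
#' @param config a [sim_config()].
#' @param case_index 1-based case number.
#' @return A [seg_mask()] ground truth.
#' @export
make_phantom <- function(config, case_index) {
  set.seed(item_seed(config$seed, case_index, 0L))
  shape <- config$shape
  grids <- coord_grids(shape)
  out <- array(0L, dim = shape)
  blocked <- array(0L, dim = shape)  # occupied + 1-voxel separation halo
  for (k in seq_along(config$classes$class_ids)) {
    rep_id <- config$classes$class_ids[[k]][1]
    n_comp <- sample(config$n_components[1]:config$n_components[2], 1L)
    placed <- 0L
    attempts <- 0L
    while (placed < n_comp && attempts < 500L) {
      attempts <- attempts + 1L
      semi <- stats::runif(3, config$comp_radius[1], config$comp_radius[2])
      margin <- semi + 2
      if (any(shape - 2 * margin <= 1)) stop("grid too small for components")
      center <- vapply(1:3, function(d)
        stats::runif(1, 1 + margin[d], shape[d] - margin[d]), 0.0)
      e <- ellipsoid_mask(grids, center, semi)
      halo <- array(cpp_dilate3d(as.integer(e), shape, 1.0), dim = shape)
      if (any(halo & blocked)) next
      out[e] <- rep_id
      blocked <- blocked | halo
      placed <- placed + 1L
    }
    if (placed < n_comp)
      stop("could not place ", n_comp, " components on this grid")
  }
  seg_mask(out, spacing = config$spacing,
           case_id = sprintf("case%03d", case_index), source_id = "gt")
}

#' Corrupt a ground truth into a candidate mask
#'
#' Applies, with lambda-scaled intensity: a random dilation or erosion of
#' each component (ball radius up to `boundary_sigma * lambda` voxels),
#' component dropout with probability `p_miss * lambda`, and insertion of
#' `Poisson(p_spurious * lambda)` small spurious blobs at random locations.
#' `lambda = 0` returns an exact copy. Deterministic given
#' `(config$seed, case_index, source_index)`.
#'
#' @param gt ground-truth [seg_mask()].
#' @param lambda corruption grade in `[0, 1]`.
#' @param config a [sim_config()].
#' @param case_index,source_index 1-based indices keying the RNG stream.
#' @return A candidate [seg_mask()].
#' @export
corrupt <- function(gt, lambda, config, case_index, source_index) {
  stopifnot(lambda >= 0, lambda <= 1)
  set.seed(item_seed(config$seed, case_index, source_index))
  shape <- dim(gt$voxels)
  out <- array(0L, dim = shape)
  spec <- config$classes
  for (k in rev(seq_along(spec$class_ids))) {  # first class wins overlaps
    rep_id <- spec$class_ids[[k]][1]
    bin <- as.integer(gt$voxels %in% spec$class_ids[[k]])
    lab <- cpp_label3d(bin, shape)
    ncomp <- attr(lab, "n_components")
    chan <- array(0L, dim = shape)
    for (comp in seq_len(ncomp)) {
      if (stats::runif(1) < config$p_miss * lambda) next
      r <- stats::runif(1, -config$boundary_sigma * lambda,
                        config$boundary_sigma * lambda)
      cm <- as.integer(lab == comp)
      if (r >= 1) cm <- cpp_dilate3d(cm, shape, r)
      else if (r <= -1) cm <- cpp_erode3d(cm, shape, -r)
      chan <- chan | array(cm, dim = shape)
    }
    out[chan] <- rep_id
  }
  n_sp <- stats::rpois(1, config$p_spurious * lambda)
  if (n_sp > 0) {
    grids <- coord_grids(shape)
    for (s in seq_len(n_sp)) {
      k <- sample(seq_along(spec$class_ids), 1L)
      radius <- stats::runif(1, 1, 2.5)
      center <- vapply(1:3, function(d)
        stats::runif(1, 1 + radius, shape[d] - radius), 0.0)
      b <- ellipsoid_mask(grids, center, rep(radius, 3))
      out[b] <- spec$class_ids[[k]][1]
    }
  }
  seg_mask(out, spacing = gt$spacing, case_id = gt$case_id,
           source_id = sprintf("alg%02d", source_index))
}

#' Generate a synthetic cohort with its truth ledger
#'
#' Draws one difficulty grade per case (shared across that case's
#' candidates, with per-source jitter), builds the phantom and the
#' corrupted candidates, and records each candidate's true class-mean Dice
#' against the ground truth — the validation ledger alarm counts are
#' checked against.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (list of [case_ensemble()] carrying ground
#'   truth) and `truth` (data.frame case_id, source_id, lambda, lambda_eff,
#'   dice).
#' @export
make_cohort <- function(config = sim_config()) {
  lambdas <- config$lambda
  if (is.null(lambdas)) {
    set.seed(item_seed(config$seed, 0L, 0L))
    lambdas <- stats::runif(config$n_cases)
  }
  cohort <- vector("list", config$n_cases)
  truth <- list(); t_i <- 0L
  for (i in seq_len(config$n_cases)) {
    gt <- make_phantom(config, i)
    cands <- vector("list", config$n_sources)
    for (j in seq_len(config$n_sources)) {
      set.seed(item_seed(config$seed, i, j, salt = 1L))
      lam <- min(max(lambdas[i] + stats::rnorm(1, 0, config$lambda_jitter_sd), 0), 1)
      cand <- corrupt(gt, lam, config, i, j)
      cands[[j]] <- cand
      d <- vapply(config$classes$class_ids, function(ids)
        dice(binarize(cand, ids), binarize(gt, ids)), 0.0)
      t_i <- t_i + 1L
      truth[[t_i]] <- data.frame(case_id = gt$case_id,
                                 source_id = cand$source_id,
                                 lambda = lambdas[i], lambda_eff = lam,
                                 dice = reduce_mean(d),
                                 stringsAsFactors = FALSE)
    }
    names(cands) <- vapply(cands, function(m) m$source_id, "")
    cohort[[i]] <- case_ensemble(gt$case_id, cands, ground_truth = gt)
  }
  list(cohort = cohort, truth = do.call(rbind, truth))
}
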