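#' Construct a segmentation mask
#'
#' A `seg_mask` is the atom every pipeline stage consumes: one 3D integer
#' label volume (0 = background) on a regular grid with per-axis voxel
#' spacing in mm, tagged with the case it belongs to and the algorithm or
#' rater that produced it.
#'
#' @param voxels 3D array of non-negative integer labels (0 = background).
#'   Numeric values within 1e-3 of an integer are rounded; anything further
#'   off is an error, since a label map encoded as floating point should
#'   still be integral up to representation noise.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param case_id,source_id identifier strings (case; algorithm/rater).
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing = c(1, 1, 1), case_id = "", source_id = "") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  if (is.double(voxels)) {
    rounded <- round(voxels)
    if (any(abs(voxels - rounded) > 1e-3))
      stop("non-integer voxel values beyond rounding tolerance 1e-3")
    voxels <- rounded
  }
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0L)) stop("label values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values")
  structure(
    list(voxels = voxels, spacing = spacing,
         case_id = as.character(case_id), source_id = as.character(source_id)),
    class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$voxels)))
  cat(sprintf("<seg_mask> case '%s' source '%s': %s grid, spacing %s mm, labels {%s}\n",
              x$case_id, x$source_id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(labs, collapse = ",")))
  invisible(x)
}

mask_shape <- function(mask) dim(mask$voxels)

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("grid mismatch: masks must share shape and spacing (co-registered grid)")
  invisible(TRUE)
}

#' Read a segmentation mask from NIfTI
#'
#' Reads a 3D integer-valued NIfTI volume (`.nii` or `.nii.gz`) and attaches
#' the header's voxel spacing. Floating-point encodings of integer label
#' maps are rounded within a tolerance of 1e-3; anything further from an
#' integer is rejected rather than silently truncated.
#'
#' @param path path to a NIfTI file.
#' @inheritParams seg_mask
#' @return A [seg_mask()].
#' @export
read_mask <- function(path, case_id = "", source_id = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  else if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D in ", path)
  spacing <- abs(RNifti::pixdim(img)[1:3])
  v <- as.array(img)
  attributes(v) <- list(dim = dim(v))  # drop NIfTI header attributes
  seg_mask(v, spacing = spacing, case_id = case_id, source_id = source_id)
}

#' Write a segmentation mask to NIfTI
#'
#' @param mask a [seg_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Define evaluation classes over label IDs
#'
#' Evaluation classes are sets of label IDs: a single label (e.g. edema) or
#' a composite region such as tumor core = enhancing + necrosis. Metrics and
#' alarms are computed per class after binarization.
#'
#' @param class_ids list of integer vectors, one label-ID set per class.
#' @param class_names character vector naming each class (unique).
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(class_ids, class_names = NULL) {
  if (!is.list(class_ids)) class_ids <- as.list(class_ids)
  class_ids <- lapply(class_ids, function(x) sort(unique(as.integer(x))))
  if (length(class_ids) == 0L) stop("`class_ids` must be non-empty")
  if (is.null(class_names))
    class_names <- vapply(class_ids, function(x) paste(x, collapse = "+"), "")
  class_names <- as.character(class_names)
  if (length(class_names) != length(class_ids))
    stop("`class_names` must parallel `class_ids`")
  if (anyDuplicated(class_names)) stop("duplicate class names")
  structure(list(class_ids = class_ids, class_names = class_names),
            class = "class_spec")
}

#' Binarize a label map against a class
#'
#' Marks 1 every voxel whose label belongs to `class_ids` (a set union, so
#' composite regions like tumor core are expressed directly), 0 elsewhere.
#' A class absent from the volume legally yields an all-zero mask.
#'
#' @param mask a [seg_mask()].
#' @param class_ids non-empty integer vector of label IDs.
#' @return A binary [seg_mask()] on the same grid.
#' @export
binarize <- function(mask, class_ids) {
  class_ids <- as.integer(class_ids)
  if (length(class_ids) == 0L) stop("`class_ids` must be non-empty")
  v <- array(as.integer(mask$voxels %in% class_ids), dim = dim(mask$voxels))
  seg_mask(v, spacing = mask$spacing, case_id = mask$case_id,
           source_id = mask$source_id)
}

#' Bundle one case's candidate segmentations
#'
#' A `case_ensemble` holds all candidate masks for one case, keyed by
#' algorithm identifier, plus an optional ground truth. Ensemble discord is
#' the method's signal, so at least two candidates are required, and all
#' members must share one co-registered grid — grids are never resampled,
#' since silent resampling could hide exactly the registration failures the
#' alarms should surface.
#'
#' @param case_id case identifier.
#' @param candidates named list of [seg_mask()], one per algorithm.
#' @param ground_truth optional [seg_mask()] on the same grid.
#' @return An object of class `case_ensemble`.
#' @export
case_ensemble <- function(case_id, candidates, ground_truth = NULL) {
  if (length(candidates) < 2L)
    stop("an ensemble needs >= 2 candidates; the method is undefined for one")
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("`candidates` must be a fully named list (source_id -> mask)")
  ref <- candidates[[1]]
  for (m in candidates[-1]) stop_if_grid_mismatch(ref, m)
  if (!is.null(ground_truth)) stop_if_grid_mismatch(ref, ground_truth)
  structure(list(case_id = as.character(case_id), candidates = candidates,
                 ground_truth = ground_truth),
            class = "case_ensemble")
}

#' Load a cohort of case ensembles from a cohort index
#'
#' The index maps each case to its candidate mask files (and optionally a
#' ground-truth file):
#' `{case_id: {sources: {name: path, ...}, gt: path}}`, given either as a
#' YAML/JSON file path or the equivalent nested list. Every case must list
#' the same roster of source names, and grids are validated within each
#' case. Relative paths resolve against the index file's directory.
#'
#' @param index path to a YAML/JSON index file, or a nested list.
#' @return A list of [case_ensemble()].
#' @export
load_cohort <- function(index) {
  base <- "."
  if (is.character(index) && length(index) == 1L) {
    if (!file.exists(index)) stop("no such index file: ", index)
    base <- dirname(index)
    index <- if (grepl("\\.json$", index)) jsonlite::read_json(index)
             else yaml::read_yaml(index)
  }
  if (length(index) == 0L) stop("empty cohort index")
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  roster <- sort(names(index[[1]]$sources))
  cohort <- vector("list", length(index))
  for (i in seq_along(index)) {
    cid <- names(index)[i]
    entry <- index[[i]]
    if (!identical(sort(names(entry$sources)), roster))
      stop("source roster mismatch in case '", cid,
           "': every case must list the same ensemble members")
    cands <- lapply(names(entry$sources), function(s)
      read_mask(resolve(entry$sources[[s]]), case_id = cid, source_id = s))
    names(cands) <- names(entry$sources)
    gt <- if (!is.null(entry$gt))
      read_mask(resolve(entry$gt), case_id = cid, source_id = "gt")
    cohort[[i]] <- case_ensemble(cid, cands, ground_truth = gt)
  }
  cohort
}

#' Write a cohort of ensembles to a directory
#'
#' Writes each mask as NIfTI (`<case>_<source>.nii.gz`, `<case>_gt.nii.gz`)
#' plus the YAML cohort index that [load_cohort()] consumes.
#'
#' @param cohort list of [case_ensemble()].
#' @param dir output directory (created if missing).
#' @return Path of the written index file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  for (ens in cohort) {
    entry <- list(sources = list())
    for (s in names(ens$candidates)) {
      fn <- sprintf("%s_%s.nii.gz", ens$case_id, s)
      write_mask(ens$candidates[[s]], file.path(dir, fn))
      entry$sources[[s]] <- fn
    }
    if (!is.null(ens$ground_truth)) {
      fn <- sprintf("%s_gt.nii.gz", ens$case_id)
      write_mask(ens$ground_truth, file.path(dir, fn))
      entry$gt <- fn
    }
    index[[ens$case_id]] <- entry
  }
  index_path <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(index, index_path)
  invisible(index_path)
}
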