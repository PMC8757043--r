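# Small mask builders used across the suite.

mk_mask <- function(dims, fg = NULL, spacing = c(1, 1, 1), label = 1L,
                    case_id = "c1", source_id = "s1") {
  v <- array(0L, dim = dims)
  if (!is.null(fg)) {
    if (is.matrix(fg)) v[fg] <- label else v[fg] <- label
  }
  seg_mask(v, spacing = spacing, case_id = case_id, source_id = source_id)
}

# Random sparse binary mask with a bounded foreground size.
random_binary <- function(dims, n_fg, spacing = c(1, 1, 1)) {
  v <- array(0L, dim = dims)
  v[sample(prod(dims), n_fg)] <- 1L
  seg_mask(v, spacing = spacing)
}

# Independent brute-force Hausdorff oracle: all-pairs max-min distance over
# foreground voxel coordinates, spacing-scaled. Pure R, no shared code with
# the package implementation.
oracle_hausdorff <- function(a, b) {
  ca <- which(a$voxels != 0L, arr.ind = TRUE)
  cb <- which(b$voxels != 0L, arr.ind = TRUE)
  if (nrow(ca) == 0L && nrow(cb) == 0L) return(NaN)
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(Inf)
  sp <- a$spacing
  d2 <- outer(seq_len(nrow(ca)), seq_len(nrow(cb)), function(i, j) {
    dx <- (ca[i, 1] - cb[j, 1]) * sp[1]
    dy <- (ca[i, 2] - cb[j, 2]) * sp[2]
    dz <- (ca[i, 3] - cb[j, 3]) * sp[3]
    dx * dx + dy * dy + dz * dz
  })
  sqrt(max(min_by_row <- apply(d2, 1, min), apply(d2, 2, min)))
}

# Generator settings that fit small grids (the defaults assume 64^3).
small_sim_config <- function(n_cases = 6, n_sources = 3, seed = 11, ...) {
  sim_config(n_cases = n_cases, n_sources = n_sources, shape = c(32, 32, 32),
             n_components = c(1, 2), comp_radius = c(2.5, 5), seed = seed, ...)
}

# Tiny fully synthetic metric table built directly from values, bypassing
# mask arithmetic, for threshold/alarm unit tests.
values_table <- function(df) {
  df$class_name <- NA_character_
  structure(list(cells = NULL,
                 reduced = df[, c("case_id", "source_id", "metric", "value")],
                 roster = sort(unique(df$source_id)),
                 class_names = "fg", metrics = unique(df$metric),
                 class_reduce = "mean"),
            class = "metric_table")
}
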