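#' Multiview extraction configuration
#'
#' Each candidate is turned into the network input by cropping axial patches
#' at several receptive-field sizes centered on the candidate voxel, resizing
#' every crop to a common side length by spline interpolation, and stacking
#' the resized views as channels (smallest crop first). Small crops resolve
#' the lesion itself; larger crops add surrounding context.
#'
#' @param crop_sizes strictly increasing pixel side lengths of the views.
#'   Default `c(20, 30, 40)`.
#' @param target_size side length of the common network input. The default
#'   224 matches full-scale training; the desk-scale profile (see
#'   [run_config()]) and the examples and tests use 32.
#' @param interpolation_order spline order for resizing: 0 (nearest),
#'   1 (linear) or 3 (cubic, default).
#' @param emit_3d if `TRUE`, [extract_archive()] additionally writes one 3D
#'   cube per view (side equal to the crop size) for bookkeeping; the 2D
#'   classifier does not consume them.
#' @return An object of class `view_config`.
#' @export
view_config <- function(crop_sizes = c(20L, 30L, 40L),
                        target_size = 224L,
                        interpolation_order = 3L,
                        emit_3d = FALSE) {
  if (length(crop_sizes) == 0L || any(crop_sizes < 2L))
    stopf("crop_sizes must be non-empty with all sizes >= 2")
  if (is.unsorted(crop_sizes, strictly = TRUE))
    stopf("crop_sizes must be strictly increasing")
  if (target_size < 2L) stopf("target_size must be >= 2")
  if (!interpolation_order %in% c(0L, 1L, 3L))
    stopf("interpolation_order must be 0 (nearest), 1 (linear) or 3 (cubic)")
  structure(list(
    crop_sizes = as.integer(crop_sizes),
    target_size = as.integer(target_size),
    interpolation_order = as.integer(interpolation_order),
    emit_3d = isTRUE(emit_3d)
  ), class = "view_config")
}

#' Crop one axial view centered on a candidate voxel
#'
#' Returns the `size` x `size` window of the axial (fixed-z) slice centered
#' at the candidate's `(y, x)`. Out-of-volume pixels are filled by edge
#' replication, which avoids injecting artificial zero-intensity structure at
#' volume borders. For even `size` the candidate voxel sits at 0-based patch
#' index `size/2` along both axes.
#'
#' @param volume 3D array indexed `[z, y, x]`.
#' @param position 0-based voxel coordinates `c(z, y, x)`.
#' @param size patch side length in pixels.
#' @return A `size` x `size` numeric matrix (rows = y, cols = x).
#' @export
crop_view <- function(volume, position, size) {
  shape <- dim(volume)
  pos1 <- as.integer(position) + 1L  # internal 1-based
  ax <- c("z", "y", "x")
  for (k in 1:3) {
    if (pos1[k] < 1L || pos1[k] > shape[k])
      stopf("candidate position out of bounds on axis %s: %d not in [0, %d]",
            ax[k], position[k], shape[k] - 1L)
  }
  c0 <- size %/% 2L  # 0-based center index within the patch
  ys <- (pos1[2] - c0):(pos1[2] - c0 + size - 1L)
  xs <- (pos1[3] - c0):(pos1[3] - c0 + size - 1L)
  ys <- pmin(pmax(ys, 1L), shape[2])  # edge replication
  xs <- pmin(pmax(xs, 1L), shape[3])
  volume[pos1[1], ys, xs, drop = TRUE]
}

# 1D interpolation of samples y (at positions 0..n-1) onto positions `at`,
# by spline order: 0 nearest, 1 linear, 3 natural cubic.
interp_1d <- function(y, at, order) {
  n <- length(y)
  if (n == 1L) return(rep(y, length(out <- at)))
  xs <- seq.int(0L, n - 1L)
  switch(as.character(order),
    "0" = y[pmin(pmax(round(at), 0), n - 1) + 1L],
    "1" = approx(xs, y, xout = at, rule = 2)$y,
    "3" = splinefun(xs, y, method = "natural")(at),
    stopf("unsupported interpolation order %s", order))
}

#' Resize a square patch by separable spline interpolation
#'
#' Both axes are resampled with the same zoom factor using an align-corners
#' grid: output pixel `i` (0-based) samples input coordinate
#' `i * (n_in - 1) / (n_out - 1)`, so the four patch corners are preserved
#' exactly and `target_size == nrow(patch)` is an exact identity.
#'
#' @param patch square numeric matrix.
#' @param target_size output side length.
#' @param order spline order: 0 nearest, 1 linear, 3 natural cubic (default).
#' @return A `target_size` x `target_size` matrix.
#' @export
resize_spline <- function(patch, target_size, order = 3L) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stopf("patch must be a square matrix, got %s x %s",
          nrow(patch), ncol(patch))
  n <- nrow(patch)
  if (n == target_size) return(patch)
  at <- seq.int(0L, target_size - 1L) * (n - 1) / (target_size - 1)
  # rows, then columns (separable)
  tmp <- apply(patch, 2L, interp_1d, at = at, order = order)   # target x n
  t(apply(tmp, 1L, interp_1d, at = at, order = order))          # target x target
}

# Per-plane z-score normalization with a variance floor so constant patches
# map to all-zeros instead of dividing by zero. SELU's self-normalizing
# behavior assumes standardized inputs.
normalize_patch <- function(m, var_floor = 1e-8) {
  mu <- mean(m)
  v <- mean((m - mu)^2)
  (m - mu) / sqrt(max(v, var_floor))
}

#' Extract the multiview network input for one candidate
#'
#' Applies [crop_view()] then [resize_spline()] for each crop size, z-score
#' normalizes each view plane (variance floor 1e-8), and stacks the views as
#' channels, smallest crop first.
#'
#' @param volume 3D array indexed `[z, y, x]`.
#' @param candidate one-row candidate data frame (columns `candidate_id`,
#'   `z`, `y`, `x`, `label`) or a list with those fields.
#' @param cfg a [view_config()].
#' @return A `multiview_patch`: list with `views` (array
#'   `target_size x target_size x n_views`), `label` (+1/-1) and
#'   `candidate_id`.
#' @export
extract_multiview <- function(volume, candidate, cfg) {
  pos <- c(candidate$z, candidate$y, candidate$x)
  views <- array(0, dim = c(cfg$target_size, cfg$target_size, length(cfg$crop_sizes)))
  for (v in seq_along(cfg$crop_sizes)) {
    p <- crop_view(volume, pos, cfg$crop_sizes[v])
    p <- resize_spline(p, cfg$target_size, cfg$interpolation_order)
    views[, , v] <- normalize_patch(p)
  }
  structure(list(views = views,
                 label = as.integer(candidate$label),
                 candidate_id = as.character(candidate$candidate_id)),
            class = "multiview_patch")
}

#' Extract multiview patches for a candidate table
#'
#' @param volume 3D array.
#' @param candidates candidate data frame (labels in \{-1, +1\}).
#' @param cfg a [view_config()].
#' @return A list of `multiview_patch` objects, in candidate-table order.
#' @export
extract_all <- function(volume, candidates, cfg) {
  lapply(seq_len(nrow(candidates)), function(i)
    extract_multiview(volume, candidates[i, ], cfg))
}

# Crop an axial 3D cube of side `size` centered on the candidate (edge
# replication), used only for archive bookkeeping when emit_3d is set.
crop_cube <- function(volume, position, size) {
  shape <- dim(volume)
  pos1 <- as.integer(position) + 1L
  c0 <- size %/% 2L
  idx <- lapply(1:3, function(k) {
    r <- (pos1[k] - c0):(pos1[k] - c0 + size - 1L)
    pmin(pmax(r, 1L), shape[k])
  })
  volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Write a multiview patch archive to disk
#'
#' One NIfTI per candidate holding the `target_size x target_size x n_views`
#' channel stack, a manifest CSV `candidate_id,label,n_views,target_size`
#' (labels 0/1 on disk), and optionally one NIfTI cube per view when
#' `cfg$emit_3d` is set.
#'
#' @inheritParams extract_all
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
extract_archive <- function(volume, candidates, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    candidate_id = character(0), label = integer(0),
    n_views = integer(0), target_size = integer(0)
  )
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    mv <- extract_multiview(volume, cand, cfg)
    write_volume(mv$views, file.path(dir, paste0(cand$candidate_id, ".nii.gz")))
    if (cfg$emit_3d) {
      for (v in seq_along(cfg$crop_sizes)) {
        cube <- crop_cube(volume, c(cand$z, cand$y, cand$x), cfg$crop_sizes[v])
        write_volume(cube, file.path(
          dir, sprintf("%s_3d_view%d.nii.gz", cand$candidate_id, v)))
      }
    }
    manifest <- rbind(manifest, data.frame(
      candidate_id = cand$candidate_id,
      label = ifelse(cand$label > 0, 1L, 0L),
      n_views = length(cfg$crop_sizes),
      target_size = cfg$target_size
    ))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Archive image-count bookkeeping
#'
#' Number of images an archive holds for a candidate set: one 2D view image
#' per candidate per crop size, doubled when 3D cubes are emitted alongside.
#'
#' @param n_candidates number of candidates.
#' @param n_views number of views (crop sizes) per candidate.
#' @param emit_3d whether one 3D cube per view is archived as well.
#' @return Integer image count.
#' @examples
#' count_archive_images(2370, 3)          # 7110 2D view images
#' count_archive_images(2370, 3, TRUE)    # 14220 with the 3D cubes
#' @export
count_archive_images <- function(n_candidates, n_views, emit_3d = FALSE) {
  as.integer(n_candidates) * as.integer(n_views) * (1L + as.integer(isTRUE(emit_3d)))
}
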