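#' Configuration for the synthetic CT phantom generator
#'
#' The phantom emulates the geometry of the nodule / nonnodule candidate
#' classification task: bright, roughly spherical Gaussian-profile nodules
#' embedded in a noisy background together with bright tubular vessel
#' segments that act as nonnodule confusers. Intensities are in arbitrary
#' units (the classifier normalizes per patch, so no Hounsfield calibration
#' is attempted).
#'
#' @param volume_shape integer vector `(z, y, x)` of voxel counts.
#' @param n_nodules number of nodule candidates (positive class).
#' @param n_nonnodules number of nonnodule candidates (negative class).
#' @param nodule_diameter_range voxels, `c(min, max)`; each nodule's diameter
#'   is drawn uniformly from this range and rendered as an isotropic Gaussian
#'   blob with `sigma = diameter / 4`.
#' @param nodule_contrast peak intensity of a nodule above background, in the
#'   same arbitrary units as `background_noise_sd`. Vessel brightness is tied
#'   to this value, so `nodule_contrast = 0` yields a pure-noise volume in
#'   which labels carry no intensity information.
#' @param background_noise_sd standard deviation of the additive Gaussian
#'   background noise.
#' @param vessel_count number of bright tubular segments (radius 1--2 voxels)
#'   added as confusers.
#' @param min_separation minimum Euclidean distance, in voxels, between any
#'   two candidate centers. Defaults to 40, the largest default view crop, so
#'   that no candidate's largest view contains another candidate.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(volume_shape = c(160L, 288L, 288L),
                           n_nodules = 50L,
                           n_nonnodules = 50L,
                           nodule_diameter_range = c(6, 14),
                           nodule_contrast = 6,
                           background_noise_sd = 1,
                           vessel_count = 30L,
                           min_separation = 40,
                           seed = 1L) {
  if (length(volume_shape) != 3L || any(volume_shape < 2))
    stopf("volume_shape must be three voxel counts >= 2")
  if (!is_count(n_nodules) || !is_count(n_nonnodules))
    stopf("n_nodules and n_nonnodules must be nonnegative counts")
  if (length(nodule_diameter_range) != 2L ||
      nodule_diameter_range[1] > nodule_diameter_range[2])
    stopf("nodule_diameter_range must be c(min, max) with min <= max")
  if (nodule_diameter_range[2] >= min(volume_shape))
    stopf("max nodule diameter must be strictly smaller than every volume dimension")
  if (background_noise_sd < 0) stopf("background_noise_sd must be >= 0")
  if (!is_count(vessel_count)) stopf("vessel_count must be a nonnegative count")
  structure(list(
    volume_shape = as.integer(volume_shape),
    n_nodules = as.integer(n_nodules),
    n_nonnodules = as.integer(n_nonnodules),
    nodule_diameter_range = as.numeric(nodule_diameter_range),
    nodule_contrast = as.numeric(nodule_contrast),
    background_noise_sd = as.numeric(background_noise_sd),
    vessel_count = as.integer(vessel_count),
    min_separation = as.numeric(min_separation),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Rejection-sample a center at least min_sep away from previously accepted
# centers. `centers` is a matrix with one (z,y,x) row per accepted center,
# 1-based voxel coordinates. Returns NULL on failure.
place_center <- function(centers, shape, min_sep, margin, max_attempts = 2000L) {
  lo <- rep(1 + margin, 3)
  hi <- shape - margin
  for (a in seq_len(max_attempts)) {
    p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
    p <- round(p)
    if (nrow(centers) == 0L) return(p)
    d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 + (centers[, 3] - p[3])^2
    if (min(d2) >= min_sep^2) return(p)
  }
  NULL
}

# Add an isotropic Gaussian blob of peak `amp` and sd `sigma` at 1-based
# center `ctr`, editing `vol` in place (returned).
paint_blob <- function(vol, ctr, sigma, amp) {
  shape <- dim(vol)
  r <- ceiling(3 * sigma)
  zi <- max(1, ctr[1] - r):min(shape[1], ctr[1] + r)
  yi <- max(1, ctr[2] - r):min(shape[2], ctr[2] + r)
  xi <- max(1, ctr[3] - r):min(shape[3], ctr[3] + r)
  dz2 <- (zi - ctr[1])^2
  dy2 <- (yi - ctr[2])^2
  dx2 <- (xi - ctr[3])^2
  d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  vol[zi, yi, xi] <- vol[zi, yi, xi] + amp * exp(-d2 / (2 * sigma^2))
  vol
}

# Paint a tubular segment as a chain of Gaussian beads combined with pmax so
# intensity along the core is flat rather than additive. Returns the edited
# layer and the bead centers (for nonnodule placement on vessels).
paint_vessel <- function(layer, p0, dir, len, radius, amp) {
  shape <- dim(layer)
  sigma <- radius / 1.5
  ts <- seq(0, len, by = 1)
  beads <- matrix(0, nrow = length(ts), ncol = 3)
  r <- ceiling(3 * sigma)
  for (i in seq_along(ts)) {
    ctr <- round(p0 + ts[i] * dir)
    beads[i, ] <- ctr
    if (any(ctr < 1 - r) || any(ctr > shape + r)) next
    zi <- max(1, ctr[1] - r):min(shape[1], ctr[1] + r)
    yi <- max(1, ctr[2] - r):min(shape[2], ctr[2] + r)
    xi <- max(1, ctr[3] - r):min(shape[3], ctr[3] + r)
    if (!length(zi) || !length(yi) || !length(xi)) next
    d2 <- outer(outer((zi - ctr[1])^2, (yi - ctr[2])^2, `+`), (xi - ctr[3])^2, `+`)
    layer[zi, yi, xi] <- pmax(layer[zi, yi, xi], amp * exp(-d2 / (2 * sigma^2)))
  }
  inside <- beads[, 1] >= 1 & beads[, 1] <= shape[1] &
    beads[, 2] >= 1 & beads[, 2] <= shape[2] &
    beads[, 3] >= 1 & beads[, 3] <= shape[3]
  list(layer = layer, beads = beads[inside, , drop = FALSE])
}

#' Generate a synthetic CT-like volume with labeled candidates
#'
#' Renders `n_nodules` Gaussian-blob nodules and `vessel_count` bright
#' tubular vessel segments into a Gaussian-noise background, then places
#' `n_nonnodules` negative candidates, half on vessel voxels (shape
#' confusers) and half on pure background, all candidate centers at least
#' `min_separation` voxels apart. The result stands in for annotated CT
#' data: every downstream stage (extraction, training, evaluation) runs on
#' it offline.
#'
#' @param config a [phantom_config()].
#' @return A list with elements
#'   \describe{
#'     \item{volume}{3D numeric array indexed `[z, y, x]` with a `spacing`
#'       attribute (voxel spacing, arbitrary units).}
#'     \item{candidates}{data frame with columns `candidate_id`, `z`, `y`,
#'       `x` (0-based voxel coordinates) and `label` (+1 nodule, -1
#'       nonnodule).}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(
#'   volume_shape = c(32, 64, 64), n_nodules = 3, n_nonnodules = 3,
#'   nodule_diameter_range = c(5, 9), vessel_count = 4,
#'   min_separation = 12, seed = 42))
#' table(ph$candidates$label)
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stopf("config must be a phantom_config")
  with_seed(config$seed, {
    shape <- config$volume_shape
    vol <- array(rnorm(prod(shape), mean = 0, sd = config$background_noise_sd),
                 dim = shape)

    # vessels first, so nodules can be placed away from every candidate,
    # and vessel bead positions are available for nonnodule placement
    vessel_layer <- array(0, dim = shape)
    all_beads <- matrix(0, nrow = 0, ncol = 3)
    if (config$vessel_count > 0L) {
      for (v in seq_len(config$vessel_count)) {
        p0 <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]), runif(1, 1, shape[3]))
        # shallow inclination to the axial plane: a vessel crossing the
        # plane steeply would show as a nodule-like disc in axial views,
        # making the label unrecoverable from 2D patches by construction
        dir <- c(0.3 * rnorm(1), rnorm(2))
        dir <- dir / sqrt(sum(dir^2))
        len <- runif(1, 0.2 * min(shape), 0.6 * min(shape))
        radius <- runif(1, 1, 2)
        pv <- paint_vessel(vessel_layer, p0, dir, len, radius,
                           amp = config$nodule_contrast)
        vessel_layer <- pv$layer
        all_beads <- rbind(all_beads, pv$beads)
      }
      vol <- vol + vessel_layer
    }

    margin <- ceiling(config$nodule_diameter_range[2] / 2)
    centers <- matrix(0, nrow = 0, ncol = 3)
    labels <- integer(0)

    for (i in seq_len(config$n_nodules)) {
      ctr <- place_center(centers, shape, config$min_separation, margin)
      if (is.null(ctr))
        stopf("placement failure: could not fit nodule %d of %d with min_separation %g in volume %s",
              i, config$n_nodules, config$min_separation,
              paste(shape, collapse = "x"))
      diam <- runif(1, config$nodule_diameter_range[1], config$nodule_diameter_range[2])
      vol <- paint_blob(vol, ctr, sigma = diam / 4, amp = config$nodule_contrast)
      centers <- rbind(centers, ctr)
      labels <- c(labels, 1L)
    }

    n_vessel_neg <- if (nrow(all_beads) > 0L) config$n_nonnodules %/% 2L else 0L
    n_bg_neg <- config$n_nonnodules - n_vessel_neg

    # vessel-voxel negatives: pick beads respecting separation
    placed_vessel_neg <- 0L
    attempts <- 0L
    max_attempts <- 2000L * max(1L, n_vessel_neg)
    while (placed_vessel_neg < n_vessel_neg && attempts < max_attempts) {
      attempts <- attempts + 1L
      b <- all_beads[sample.int(nrow(all_beads), 1L), ]
      d2 <- (centers[, 1] - b[1])^2 + (centers[, 2] - b[2])^2 + (centers[, 3] - b[3])^2
      if (nrow(centers) == 0L || min(d2) >= config$min_separation^2) {
        centers <- rbind(centers, b)
        labels <- c(labels, -1L)
        placed_vessel_neg <- placed_vessel_neg + 1L
      }
    }
    n_bg_neg <- n_bg_neg + (n_vessel_neg - placed_vessel_neg)

    for (i in seq_len(n_bg_neg)) {
      ctr <- place_center(centers, shape, config$min_separation, margin = 0)
      if (is.null(ctr))
        stopf("placement failure: could not fit nonnodule candidate %d of %d with min_separation %g",
              i, config$n_nonnodules, config$min_separation)
      centers <- rbind(centers, ctr)
      labels <- c(labels, -1L)
    }

    attr(vol, "spacing") <- c(1, 1, 1)
    candidates <- data.frame(
      candidate_id = sprintf("cand-%04d", seq_along(labels)),
      z = as.integer(centers[, 1] - 1L),  # 0-based on the interface
      y = as.integer(centers[, 2] - 1L),
      x = as.integer(centers[, 3] - 1L),
      label = labels,
      stringsAsFactors = FALSE
    )
    list(volume = vol, candidates = candidates)
  })
}

#' Read and write phantom volumes and candidate tables
#'
#' Volumes are stored as NIfTI-1 (via \pkg{RNifti}); candidate tables as CSV
#' with header `candidate_id,z,y,x,label`, label coded 0/1 on disk and
#' mapped to -1/+1 in memory.
#'
#' @param volume 3D array as produced by [generate_phantom()].
#' @param path file path (`.nii` or `.nii.gz` for volumes, `.csv` for tables).
#' @return `read_volume()` returns a 3D array; `read_candidates()` a
#'   candidate data frame with labels in \{-1, +1\}.
#' @name phantom_io
NULL

#' @rdname phantom_io
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(volume)), path)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "spacing") <- c(1, 1, 1)
  vol
}

#' @rdname phantom_io
#' @param candidates candidate data frame with labels in \{-1, +1\}.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  out$label <- ifelse(out$label > 0, 1L, 0L)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_candidates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("candidate_id", "z", "y", "x", "label")
  if (!all(need %in% names(df)))
    stopf("candidate table must have columns %s", paste(need, collapse = ", "))
  df$label <- ifelse(df$label > 0, 1L, -1L)
  df[, need]
}
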