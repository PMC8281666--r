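#' Mean and SD of image intensity over a mask
#'
#' Population SD (n divisor) is used throughout the pipeline, matching how
#' a region's noise level enters the mean +/- k SD threshold rules.
#'
#' @param image A `sim_image` or numeric array.
#' @param mask Logical array of the same dimensions, non-empty.
#' @return Object of class `region_stats`: `mean_si`, `sd_si`, `n_pixels`.
#' @examples
#' region_stats(array(c(4, 6), c(2, 1, 1)), array(TRUE, c(2, 1, 1)))
#' @export
region_stats <- function(image, mask) {
  img <- as_intensity(image)
  m <- check_mask(mask, dim(img))
  x <- img[m]
  if (length(x) == 0) stop("mask selects no pixels", call. = FALSE)
  mu <- mean(x)
  structure(list(mean_si = mu,
                 sd_si = sqrt(mean((x - mu)^2)),
                 n_pixels = length(x)),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region: mean %.4g, SD %.4g over %d px\n",
              x$mean_si, x$sd_si, x$n_pixels))
  invisible(x)
}

#' Background-air ROI mask
#'
#' Square ROI in the top-left image corner, guaranteed free of phantom
#' tissue for default geometries, used to estimate the noise floor
#' `sigma_air` of each magnitude image.
#'
#' @param dims Image dimensions (2 or 3 elements).
#' @param size ROI side length in pixels.
#' @return Logical array.
#' @export
air_roi_mask <- function(dims, size = 40L) {
  if (size < 2 || size > min(dims[1:2])) {
    stop("air ROI size out of range for these image dimensions", call. = FALSE)
  }
  m <- array(FALSE, dim = dims)
  if (length(dims) == 2) m[seq_len(size), seq_len(size)] <- TRUE
  else m[seq_len(size), seq_len(size), ] <- TRUE
  m
}

#' Place the remote-myocardium reference ROI
#'
#' Remote myocardium is the region free of hyperintensity on LGE; the ROI
#' is a contiguous angular sector of myocardium placed diametrically
#' opposite the infarct's (circular mean) angle, excluding all MI pixels.
#' With no infarct the sector sits opposite the reference insertion angle.
#' `jitter_seed` rotates (+/- 15 deg) and rescales (0.85-1.15) the sector
#' to emulate reader-to-reader ROI placement variability; `rotation` and
#' `width_scale` set the jitter explicitly instead.
#'
#' @param lge LGE `sim_image` (carried for interface symmetry; placement
#'   uses the masks).
#' @param myo_mask Logical myocardium stack.
#' @param mi_mask Logical MI-zone stack (excluded from the ROI).
#' @param jitter_seed Optional integer seed for random jitter.
#' @param width Nominal angular width of the ROI, degrees.
#' @param ref_angle Reference insertion angle, degrees.
#' @param rotation,width_scale Explicit jitter (override the seed draws).
#' @return Logical ROI stack with attributes `center_angle` and `width`.
#' @export
select_remote_roi <- function(lge, myo_mask, mi_mask, jitter_seed = NULL,
                              width = 60, ref_angle = 0,
                              rotation = NULL, width_scale = NULL) {
  img <- as_intensity(lge)
  myo <- check_mask(myo_mask, dim(img), "myo_mask")
  mi <- check_mask(mi_mask, dim(img), "mi_mask")
  myo2 <- myo[, , 1, drop = TRUE]
  mi2 <- mi[, , 1, drop = TRUE]
  if (!any(myo2)) stop("myocardium mask is empty", call. = FALSE)
  if (all(mi2[myo2])) stop("MI covers the entire myocardium; no remote region",
                           call. = FALSE)

  idx <- which(myo2, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  n <- nrow(myo2)
  row0 <- matrix(0:(n - 1), n, ncol(myo2))
  col0 <- t(matrix(0:(ncol(myo2) - 1), ncol(myo2), n))
  theta <- (atan2(-(row0 - (center[1] - 1)), col0 - (center[2] - 1)) * 180 / pi -
              ref_angle) %% 360

  mi_angle <- if (any(mi2)) circ_mean_deg(theta[mi2]) else ref_angle
  if (is.null(rotation) || is.null(width_scale)) {
    jit <- if (is.null(jitter_seed)) c(0, 1) else {
      with_seed(jitter_seed, c(stats::runif(1, -15, 15), stats::runif(1, 0.85, 1.15)))
    }
    rotation <- rotation %||% jit[1]
    width_scale <- width_scale %||% jit[2]
  }
  roi_center <- (mi_angle + 180 + rotation) %% 360
  roi2 <- myo2 & !mi2 & in_sector(theta, roi_center, width * width_scale)
  if (!any(roi2)) stop("remote ROI is empty; widen the sector", call. = FALSE)

  roi <- array(roi2, dim = dim(myo))
  attr(roi, "center_angle") <- roi_center
  attr(roi, "width") <- width * width_scale
  roi
}

# threshold comparison used by both detectors: inclusive per the "at least
# k SD" rule, strict in the degenerate sd = 0 case so that pixels exactly
# at the (noise-free) remote mean are not swept in by the tie
above_threshold <- function(x, thr, sd) if (sd > 0) x >= thr else x > thr
below_threshold <- function(x, thr, sd) if (sd > 0) x <= thr else x < thr

#' Delineate the infarct (MI) zone on LGE
#'
#' Flags myocardial pixels whose LGE intensity is at least
#' `k_sd` standard deviations above the remote-ROI mean
#' (threshold `mean + k_sd * SD`, inclusive).
#'
#' @param lge LGE `sim_image` or array.
#' @param myo_mask Logical myocardium stack.
#' @param remote_roi Logical remote-ROI stack (see [select_remote_roi()]).
#' @param k_sd Threshold multiplier (default 5).
#' @return List: `mask` (logical stack), `threshold`, `remote_stats`,
#'   `k_sd`, and `degenerate` (TRUE when the remote SD is zero).
#' @export
detect_mi_zone <- function(lge, myo_mask, remote_roi, k_sd = 5) {
  img <- as_intensity(lge)
  myo <- check_mask(myo_mask, dim(img), "myo_mask")
  stats <- region_stats(img, remote_roi)
  thr <- stats$mean_si + k_sd * stats$sd_si
  mask <- myo & above_threshold(img, thr, stats$sd_si)
  list(mask = mask, threshold = thr, remote_stats = stats, k_sd = k_sd,
       degenerate = stats$sd_si == 0)
}

# 4-connected component labelling of a logical matrix (union-find over the
# foreground pixels only; candidate sets are small).
label_components_2d <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(idx)) {
    p <- idx[k]
    up <- p - 1L
    if (p %% nr != 1L && up >= 1L && pos[up] > 0L) {
      a <- find(k); b <- find(pos[up])
      if (a != b) parent[a] <- b
    }
    left <- p - nr
    if (left >= 1L && pos[left] > 0L) {
      a <- find(k); b <- find(pos[left])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# drop in-plane 4-connected components smaller than min_px, slice by slice
filter_small_components <- function(mask, min_px) {
  if (min_px <= 1) return(mask)
  out <- mask
  for (s in seq_len(dim(mask)[3])) {
    lab <- label_components_2d(mask[, , s])
    if (max(lab) == 0) next
    sizes <- tabulate(lab)
    keep <- lab > 0 & sizes[pmax(lab, 1L)] >= min_px
    out[, , s] <- keep
  }
  out
}

#' Detect the hemorrhagic (IMH) core within the infarct
#'
#' Flags MI pixels whose T2*-weighted intensity is at least `k_sd` SD below
#' the remote-ROI mean (threshold `mean - k_sd * SD`, inclusive), then
#' discards in-plane 4-connected components smaller than
#' `min_core_pixels` (suppressing single-pixel noise speckle). Because
#' every retained pixel satisfies the criterion, each retained core's mean
#' intensity necessarily does too. The output is invariant to any
#' monotone affine rescaling applied jointly to the image and remote ROI.
#'
#' @param t2sw T2*-weighted `sim_image` or array.
#' @param mi_mask Logical MI-zone stack, non-empty.
#' @param remote_roi Logical remote-ROI stack.
#' @param min_core_pixels Minimum retained core size, pixels.
#' @param k_sd Threshold multiplier (default 2).
#' @return List: `mask`, `threshold`, `remote_stats`, `k_sd`,
#'   `min_core_pixels`.
#' @export
detect_imh <- function(t2sw, mi_mask, remote_roi, min_core_pixels = 2L,
                       k_sd = 2) {
  img <- as_intensity(t2sw)
  mi <- check_mask(mi_mask, dim(img), "mi_mask")
  if (!any(mi)) stop("MI mask is empty", call. = FALSE)
  stats <- region_stats(img, remote_roi)
  thr <- stats$mean_si - k_sd * stats$sd_si
  cand <- mi & below_threshold(img, thr, stats$sd_si)
  mask <- filter_small_components(cand, min_core_pixels)
  list(mask = mask, threshold = thr, remote_stats = stats, k_sd = k_sd,
       min_core_pixels = min_core_pixels)
}

#' IMH extent as percent of LV myocardial volume
#'
#' `100 * (IMH voxel volume) / (myocardial voxel volume)` over the imaged
#' stack (uniform voxels, slice-matched masks).
#'
#' @param imh_mask Logical IMH stack.
#' @param lv_myo_mask Logical LV myocardium stack, non-empty.
#' @return Percent in [0, 100].
#' @export
imh_extent <- function(imh_mask, lv_myo_mask) {
  imh <- as_intensity(imh_mask)
  myo <- as_intensity(lv_myo_mask)
  if (!identical(dim(imh), dim(myo))) {
    stop("IMH and myocardium masks must be slice-matched", call. = FALSE)
  }
  n_myo <- sum(myo)
  if (n_myo == 0) stop("myocardium mask is empty", call. = FALSE)
  100 * sum(imh) / n_myo
}

#' Reader profile for segmentation
#'
#' Emulates reader behavior as a remote-ROI placement jitter plus a small
#' perturbation of the threshold multipliers: the reader applies
#' `(5 + dk)`-SD and `(2 + dk)`-SD rules with `dk` drawn uniformly in
#' +/- 0.1 SD units, and rotates/rescales the remote sector. A profile with
#' no seed and zero jitter is the idealized reader.
#'
#' @param jitter_seed Optional seed; when given, `rotation`, `width_scale`
#'   and `dk` are drawn from it.
#' @param rotation ROI rotation, degrees.
#' @param width_scale ROI width multiplier.
#' @param dk Additive perturbation of both SD multipliers.
#' @return Object of class `reader_profile`.
#' @export
reader_profile <- function(jitter_seed = NULL, rotation = 0, width_scale = 1,
                           dk = 0) {
  if (!is.null(jitter_seed)) {
    draws <- with_seed(jitter_seed, stats::runif(3))
    rotation <- -15 + 30 * draws[1]
    width_scale <- 0.85 + 0.30 * draws[2]
    dk <- -0.1 + 0.2 * draws[3]
  }
  structure(list(jitter_seed = jitter_seed, rotation = rotation,
                 width_scale = width_scale, dk = dk),
            class = "reader_profile")
}

#' Segment one arm of a simulated subject
#'
#' Runs the full quantification chain for one T2*-weighted arm: remote ROI
#' placement on the (true) myocardium excluding the (true) MI zone, infarct
#' delineation on LGE with the mean + 5 SD rule, hemorrhage detection
#' within the detected MI zone with the mean - 2 SD rule, and IMH extent
#' normalized by the true LV myocardial volume (myocardial contours are
#' assumed accurate; thresholds are where reader variability enters).
#'
#' @param subject A [simulate_subject()] result.
#' @param arm `"bright"` or `"dark"`.
#' @param reader A [reader_profile()].
#' @param roi_width Nominal remote-ROI angular width, degrees.
#' @param min_core_pixels Minimum retained IMH core size.
#' @return Object of class `segmentation_result`: `mi_mask`, `imh_mask`,
#'   `mi_threshold`, `imh_threshold`, `remote_stats` (T2*-weighted arm),
#'   `remote_roi`, `imh_extent_pct`, `arm`, `reader`.
#' @export
quantify_subject <- function(subject, arm = c("bright", "dark"),
                             reader = reader_profile(), roi_width = 60,
                             min_core_pixels = 2L) {
  stopifnot(inherits(subject, "sim_subject"), inherits(reader, "reader_profile"))
  arm <- match.arg(arm)
  truth <- subject$truth
  geom <- subject$label_map$geometry
  roi <- select_remote_roi(subject$lge, truth$masks$lv_myo, truth$masks$mi_zone,
                           width = roi_width,
                           ref_angle = geom$ref_insertion_angle,
                           rotation = reader$rotation,
                           width_scale = reader$width_scale)
  mi_det <- detect_mi_zone(subject$lge, truth$masks$lv_myo, roi,
                           k_sd = 5 + reader$dk)
  image <- subject[[arm]]
  imh_det <- detect_imh(image, mi_det$mask, roi,
                        min_core_pixels = min_core_pixels,
                        k_sd = 2 + reader$dk)
  structure(list(mi_mask = mi_det$mask, imh_mask = imh_det$mask,
                 mi_threshold = mi_det$threshold,
                 imh_threshold = imh_det$threshold,
                 remote_stats = imh_det$remote_stats,
                 remote_roi = roi,
                 imh_extent_pct = imh_extent(imh_det$mask, truth$masks$lv_myo),
                 arm = arm, reader = reader),
            class = "segmentation_result")
}
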