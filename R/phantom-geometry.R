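#' Tissue class codes used in phantom label maps
#'
#' Integer codes for the six tissue classes of the left-ventricular
#' short-axis phantom. `AIR` is background; `BLOOD_FLOWING` is chamber blood
#' that is replaced between the two inversion pulses of a dark-blood (DIR)
#' preparation; `BLOOD_STAGNANT` is the slow-moving annular blood layer
#' adjacent to the infarcted endocardial border, which experiences both
#' pulses like in-slice tissue; `REMOTE_MYO` is uninjured myocardium;
#' `MI` is the infarct sector and `IMH` the hemorrhagic core nested inside it.
#'
#' @format Named integer vector of length 6.
#' @export
TISSUE_CLASSES <- c(AIR = 0L, BLOOD_FLOWING = 1L, BLOOD_STAGNANT = 2L,
                    REMOTE_MYO = 3L, MI = 4L, IMH = 5L)

#' Define the short-axis LV phantom geometry
#'
#' The phantom is a circular LV annulus in each short-axis slice: blood pool
#' inside `endo_radius`, myocardium between `endo_radius` and `epi_radius`,
#' air elsewhere. An infarct (MI) occupies an angular sector of the
#' myocardium from the endocardium outward to a fraction `mi_transmurality`
#' of the wall; a hemorrhagic core (IMH) occupies a nested sector covering
#' the innermost `imh_radial_span` fraction of the MI wall depth
#' (hemorrhage emanates from the subendocardium). A thin annular layer of
#' stagnant blood hugs the MI endocardial border. All slices share the same
#' in-plane geometry (mid-ventricular short-axis stack).
#'
#' Angles are measured counter-clockwise in degrees from
#' `ref_insertion_angle` (the anterior RV insertion reference used for the
#' AHA partition); pixel membership is decided at pixel centers with
#' 0-based pixel coordinates, rows counting downward.
#'
#' @param grid_size Pixels per image side.
#' @param pixel_spacing In-plane pixel size, mm.
#' @param n_slices Number of short-axis slices.
#' @param lv_center LV center `(row, col)` in 0-based pixel units; defaults
#'   to the grid center.
#' @param endo_radius,epi_radius Endocardial / epicardial radii, mm.
#' @param mi_angular_span Total angular width of the MI sector, degrees.
#' @param mi_center_angle Center angle of the MI sector, degrees CCW from
#'   the reference insertion angle.
#' @param mi_transmurality Fraction (0, 1] of wall depth infarcted, measured
#'   from the endocardium outward.
#' @param imh_angular_span Angular width of the IMH core, degrees; must not
#'   exceed `mi_angular_span`.
#' @param imh_radial_span Fraction [0, 1] of the MI wall depth occupied by
#'   the IMH core, from the endocardium outward.
#' @param stagnant_layer_thickness Thickness (mm) of the stagnant blood
#'   layer adjacent to the MI endocardial border; 0 disables it.
#' @param ref_insertion_angle Reference angle, degrees.
#'
#' @return An object of class `phantom_geometry`.
#' @seealso [build_label_map()]
#' @export
phantom_geometry <- function(grid_size = 192L,
                             pixel_spacing = 1,
                             n_slices = 6L,
                             lv_center = NULL,
                             endo_radius = 18,
                             epi_radius = 28,
                             mi_angular_span = 100,
                             mi_center_angle = 90,
                             mi_transmurality = 0.8,
                             imh_angular_span = 60,
                             imh_radial_span = 0.6,
                             stagnant_layer_thickness = 2,
                             ref_insertion_angle = 0) {
  grid_size <- as.integer(grid_size)
  n_slices <- as.integer(n_slices)
  lv_center <- lv_center %||% rep((grid_size - 1) / 2, 2)

  if (grid_size < 8) stop("`grid_size` must be at least 8 pixels", call. = FALSE)
  if (pixel_spacing <= 0) stop("`pixel_spacing` must be positive", call. = FALSE)
  if (n_slices < 1) stop("`n_slices` must be at least 1", call. = FALSE)
  if (endo_radius <= 0) stop("`endo_radius` must be positive", call. = FALSE)
  if (endo_radius >= epi_radius) {
    stop("`endo_radius` must be strictly smaller than `epi_radius`", call. = FALSE)
  }
  if (mi_angular_span < 0 || imh_angular_span < 0) {
    stop("angular spans must be non-negative", call. = FALSE)
  }
  if (imh_angular_span > mi_angular_span) {
    stop("`imh_angular_span` must not exceed `mi_angular_span`", call. = FALSE)
  }
  if (mi_transmurality <= 0 || mi_transmurality > 1) {
    stop("`mi_transmurality` must be in (0, 1]", call. = FALSE)
  }
  if (imh_radial_span < 0 || imh_radial_span > 1) {
    stop("`imh_radial_span` must be in [0, 1]", call. = FALSE)
  }
  if (stagnant_layer_thickness < 0) {
    stop("`stagnant_layer_thickness` must be non-negative", call. = FALSE)
  }
  fov_margin <- min(lv_center[1], lv_center[2],
                    grid_size - 1 - lv_center[1], grid_size - 1 - lv_center[2])
  if (epi_radius / pixel_spacing > fov_margin) {
    stop("`epi_radius` does not fit inside the field of view", call. = FALSE)
  }

  structure(list(grid_size = grid_size, pixel_spacing = pixel_spacing,
                 n_slices = n_slices, lv_center = lv_center,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 mi_angular_span = mi_angular_span,
                 mi_center_angle = mi_center_angle,
                 mi_transmurality = mi_transmurality,
                 imh_angular_span = imh_angular_span,
                 imh_radial_span = imh_radial_span,
                 stagnant_layer_thickness = stagnant_layer_thickness,
                 ref_insertion_angle = ref_insertion_angle),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("LV phantom geometry:", x$grid_size, "x", x$grid_size, "px @",
      x$pixel_spacing, "mm,", x$n_slices, "slice(s)\n")
  cat(sprintf("  wall %g-%g mm; MI %g deg sector @ %g deg, transmurality %.2f\n",
              x$endo_radius, x$epi_radius, x$mi_angular_span,
              x$mi_center_angle, x$mi_transmurality))
  cat(sprintf("  IMH %g deg, radial span %.2f; stagnant layer %g mm\n",
              x$imh_angular_span, x$imh_radial_span, x$stagnant_layer_thickness))
  invisible(x)
}

# Polar coordinates (radius mm, CCW angle deg from the reference insertion
# angle) of every pixel center in one slice.
polar_grid <- function(geometry) {
  n <- geometry$grid_size
  sp <- geometry$pixel_spacing
  row0 <- matrix(0:(n - 1), n, n)            # row index, 0-based
  col0 <- t(row0)
  dx <- (col0 - geometry$lv_center[2]) * sp
  dy <- -(row0 - geometry$lv_center[1]) * sp # rows count downward; y points up
  list(r = sqrt(dx^2 + dy^2),
       theta = (atan2(dy, dx) * 180 / pi - geometry$ref_insertion_angle) %% 360)
}

#' Build the tissue label map of the phantom
#'
#' Rasterizes the geometry into an integer image stack, one [TISSUE_CLASSES]
#' code per pixel, membership decided at pixel centers (radius inclusive at
#' the inner boundary, exclusive at the outer).
#'
#' @param geometry A [phantom_geometry()].
#' @return Object of class `label_map`: list with `labels` (integer array
#'   `grid_size x grid_size x n_slices`) and `geometry`.
#' @examples
#' lm <- build_label_map(phantom_geometry(grid_size = 96, pixel_spacing = 2))
#' table(lm$labels[, , 1])
#' @export
build_label_map <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  g <- geometry
  pg <- polar_grid(g)
  r <- pg$r
  theta <- pg$theta

  lab <- matrix(TISSUE_CLASSES[["AIR"]], g$grid_size, g$grid_size)

  myo <- r >= g$endo_radius & r < g$epi_radius
  lab[myo] <- TISSUE_CLASSES[["REMOTE_MYO"]]

  wall <- g$epi_radius - g$endo_radius
  mi_outer <- g$endo_radius + g$mi_transmurality * wall
  in_mi_sector <- in_sector(theta, g$mi_center_angle, g$mi_angular_span)
  mi <- myo & in_mi_sector & r < mi_outer
  lab[mi] <- TISSUE_CLASSES[["MI"]]

  imh_outer <- g$endo_radius + g$imh_radial_span * g$mi_transmurality * wall
  imh <- mi & in_sector(theta, g$mi_center_angle, g$imh_angular_span) & r < imh_outer
  lab[imh] <- TISSUE_CLASSES[["IMH"]]

  blood <- r < g$endo_radius
  lab[blood] <- TISSUE_CLASSES[["BLOOD_FLOWING"]]
  if (g$stagnant_layer_thickness > 0 && g$mi_angular_span > 0) {
    stag <- blood & r >= g$endo_radius - g$stagnant_layer_thickness & in_mi_sector
    lab[stag] <- TISSUE_CLASSES[["BLOOD_STAGNANT"]]
  }

  labels <- array(lab, dim = c(g$grid_size, g$grid_size, g$n_slices))
  structure(list(labels = labels, geometry = g), class = "label_map")
}

#' Ground-truth masks and true IMH extent of a label map
#'
#' @param label_map A [build_label_map()] result.
#' @return Object of class `ground_truth`: list with per-class logical
#'   `masks` (plus `mi_zone` = MI together with its IMH core, and `lv_myo` =
#'   all myocardium) and `true_imh_extent`, the IMH volume as percent of the
#'   LV myocardial volume over the imaged stack.
#' @export
ground_truth <- function(label_map) {
  stopifnot(inherits(label_map, "label_map"))
  lab <- label_map$labels
  masks <- lapply(TISSUE_CLASSES, function(code) lab == code)
  masks$mi_zone <- masks$MI | masks$IMH
  masks$lv_myo <- masks$REMOTE_MYO | masks$MI | masks$IMH
  n_myo <- sum(masks$lv_myo)
  if (n_myo == 0) stop("label map contains no myocardium", call. = FALSE)
  structure(list(masks = masks,
                 true_imh_extent = 100 * sum(masks$IMH) / n_myo,
                 geometry = label_map$geometry),
            class = "ground_truth")
}
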