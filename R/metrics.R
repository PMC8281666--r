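#' Relative SNR of the dark-blood versus bright-blood arm
#'
#' `100 * (SI_remote_DB / sigma_air_DB) / (SI_remote_BB / sigma_air_BB)`,
#' on the percent scale. Each arm self-normalizes by its own background-air
#' noise, so the measure is invariant to a global intensity rescaling of
#' either arm alone; the air SD is used without Rayleigh correction since
#' the correction factor cancels in the ratio.
#'
#' @param remote_db,remote_bb [region_stats()] of remote myocardium on the
#'   dark and bright arms.
#' @param air_db,air_bb [region_stats()] of background air on each arm.
#' @return Percent.
#' @examples
#' rs <- function(m, s) structure(list(mean_si = m, sd_si = s, n_pixels = 100),
#'                                class = "region_stats")
#' relative_snr(rs(80, 1), rs(0, 2), rs(100, 1), rs(0, 2)) # 80
#' @export
relative_snr <- function(remote_db, air_db, remote_bb, air_bb) {
  if (air_db$sd_si <= 0) stop("zero air SD in the dark-blood arm", call. = FALSE)
  if (air_bb$sd_si <= 0) stop("zero air SD in the bright-blood arm", call. = FALSE)
  if (remote_db$mean_si <= 0 || remote_bb$mean_si <= 0) {
    stop("remote means must be positive", call. = FALSE)
  }
  100 * (remote_db$mean_si / air_db$sd_si) / (remote_bb$mean_si / air_bb$sd_si)
}

#' Relative CNR between IMH and remote myocardium, dark versus bright
#'
#' `100 * ((SI_remote_DB - SI_IMH_DB) / sigma_air_DB) /
#'        ((SI_remote_BB - SI_IMH_BB) / sigma_air_BB)`.
#'
#' @param remote_db,imh_db,air_db Dark-arm [region_stats()] of remote
#'   myocardium, the IMH region, and background air.
#' @param remote_bb,imh_bb,air_bb The bright-arm counterparts.
#' @return Percent.
#' @export
relative_cnr <- function(remote_db, imh_db, air_db, remote_bb, imh_bb, air_bb) {
  if (air_db$sd_si <= 0) stop("zero air SD in the dark-blood arm", call. = FALSE)
  if (air_bb$sd_si <= 0) stop("zero air SD in the bright-blood arm", call. = FALSE)
  contrast_bb <- remote_bb$mean_si - imh_bb$mean_si
  if (contrast_bb == 0) {
    stop("bright-arm IMH/remote contrast is zero; relative CNR undefined",
         call. = FALSE)
  }
  100 * ((remote_db$mean_si - imh_db$mean_si) / air_db$sd_si) /
    (contrast_bb / air_bb$sd_si)
}

#' Coefficient of variation of a region
#'
#' `sigma / SI`: region SD over region mean. Scale-invariant.
#'
#' @param stats A [region_stats()] result.
#' @return Dimensionless COV.
#' @export
region_cov <- function(stats) {
  if (stats$mean_si == 0) stop("region mean is zero; COV undefined", call. = FALSE)
  stats$sd_si / stats$mean_si
}

#' Paired signal metrics for one subject
#'
#' Assembles the per-subject metric record for a slice-matched
#' bright/dark pair: remote mean from each arm's segmentation ROI, IMH mean
#' over each arm's detected core (falling back to the true core when an
#' arm detects nothing), air SD from a corner background ROI, relative
#' SNR/CNR, per-arm remote COV, and the per-subject COV excess
#' `100 * (COV_DB - COV_BB) / COV_BB`.
#'
#' @param subject A [simulate_subject()] result.
#' @param seg_bright,seg_dark [quantify_subject()] results for the two arms
#'   (same reader).
#' @param air_size Side of the square background-air ROI, pixels.
#' @return One-row `data.frame` (a `MetricRecord`).
#' @export
subject_signal_metrics <- function(subject, seg_bright, seg_dark,
                                   air_size = 40L) {
  stopifnot(inherits(subject, "sim_subject"))
  dims <- dim(subject$bright$intensity)
  air <- air_roi_mask(dims, air_size)
  if (!all(subject$truth$masks$AIR[air])) {
    stop("background-air ROI overlaps phantom tissue; reduce `air_size`",
         call. = FALSE)
  }
  imh_region <- function(seg) {
    if (any(seg$imh_mask)) seg$imh_mask else subject$truth$masks$IMH
  }
  rem_bb <- region_stats(subject$bright, seg_bright$remote_roi)
  rem_db <- region_stats(subject$dark, seg_dark$remote_roi)
  imh_bb <- region_stats(subject$bright, imh_region(seg_bright))
  imh_db <- region_stats(subject$dark, imh_region(seg_dark))
  air_bb <- region_stats(subject$bright, air)
  air_db <- region_stats(subject$dark, air)
  cov_bb <- region_cov(rem_bb)
  cov_db <- region_cov(rem_db)
  data.frame(si_remote_db = rem_db$mean_si, si_remote_bb = rem_bb$mean_si,
             si_imh_db = imh_db$mean_si, si_imh_bb = imh_bb$mean_si,
             sigma_air_db = air_db$sd_si, sigma_air_bb = air_bb$sd_si,
             relative_snr_pct = relative_snr(rem_db, air_db, rem_bb, air_bb),
             relative_cnr_pct = relative_cnr(rem_db, imh_db, air_db,
                                             rem_bb, imh_bb, air_bb),
             cov_db = cov_db, cov_bb = cov_bb,
             cov_excess_pct = 100 * (cov_db - cov_bb) / cov_bb)
}
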