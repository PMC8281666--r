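#' Spoiled gradient-echo saturation factor
#'
#' Steady-state longitudinal term `(1 - E1) / (1 - E1 cos(alpha))` with
#' `E1 = exp(-RR/T1)` for a spoiled gradient-recalled echo triggered once
#' per heartbeat.
#'
#' @param T1 Longitudinal relaxation time, ms.
#' @param RR Repetition (R-R) interval, ms.
#' @param flip_angle Flip angle, degrees.
#' @return Dimensionless factor in (0, 1].
#' @keywords internal
gre_saturation <- function(T1, RR, flip_angle) {
  E1 <- exp(-RR / T1)
  (1 - E1) / (1 - E1 * cos(deg2rad(flip_angle)))
}

#' Longitudinal recovery fraction after a DIR preparation
#'
#' Fraction of the available (steady-state) longitudinal magnetization
#' present at the readout, TI milliseconds after a double-inversion-recovery
#' pair. In-slice tissue and stagnant blood experience both pulses:
#' `Mprep = kappa (2 eta_ns - 1)(2 eta_sel - 1) M`. Blood flowing into the
#' slice between the pulses experiences only the non-selective inversion:
#' `Mprep = kappa (1 - 2 eta_ns) M`, so it recovers through a null near
#' `TI = T1 ln 2` — the blood-nulling mechanism of dark-blood imaging.
#' Recovery is mono-exponential toward the steady state:
#' `f = 1 - (1 - Mprep/M) exp(-TI/T1)` (signed; may be negative for flowing
#' blood short of its null).
#'
#' For in-slice tissue the fraction equals the dark-to-bright signal ratio
#' of that tissue, which is what the field-strength comparison turns on:
#' it is non-decreasing in `kappa` and in each efficiency on [0.5, 1], is
#' at most 1, and reaches 1 only for a perfect preparation with full
#' recovery.
#'
#' @param T1 Longitudinal relaxation time, ms.
#' @param TI Inversion time, ms.
#' @param eta_nonsel,eta_sel Inversion efficiencies in [0.5, 1].
#' @param kappa Lumped attenuation in (0, 1].
#' @param flowing Logical: replaced between pulses (chamber blood)?
#' @return Signed recovery fraction (<= 1).
#' @export
dir_recovery_fraction <- function(T1, TI, eta_nonsel, eta_sel, kappa,
                                  flowing = FALSE) {
  if (any(T1 <= 0)) stop("`T1` must be positive", call. = FALSE)
  mprep <- if (flowing) {
    kappa * (1 - 2 * eta_nonsel)
  } else {
    kappa * (2 * eta_nonsel - 1) * (2 * eta_sel - 1)
  }
  1 - (1 - mprep) * exp(-TI / T1)
}

#' Dark-to-bright remote signal ratio for in-slice tissue
#'
#' Convenience wrapper around [dir_recovery_fraction()] for monotonicity
#' sweeps and preset calibration: the dark-blood and bright-blood arms
#' share the readout, so for in-slice tissue the signal ratio reduces to
#' the DIR recovery fraction.
#'
#' @inheritParams dir_recovery_fraction
#' @return Ratio in (0, 1] for efficiencies in [0.5, 1].
#' @export
dark_bright_ratio <- function(T1 = 950, TI = 600, eta_nonsel = 0.92,
                              eta_sel = eta_nonsel, kappa = 0.80) {
  dir_recovery_fraction(T1, TI, eta_nonsel, eta_sel, kappa, flowing = FALSE)
}

#' Closed-form steady-state signal of one tissue
#'
#' Magnitude signal of a spoiled gradient-echo readout:
#' `S = PD sin(alpha) SS exp(-TE/T2*)` with `SS` the saturation factor
#' ([gre_saturation()]). For the dark-blood arm the DIR preparation scales
#' the longitudinal magnetization by the recovery fraction
#' ([dir_recovery_fraction()]); the returned value is the magnitude
#' (non-negative), so flowing blood is nulled at `TI = T1 ln 2` for an
#' ideal inversion.
#'
#' @param tissue List with `T1`, `T2star`, `PD` and optionally `flowing`
#'   (one entry of [tissue_presets()]).
#' @param seq A [sequence_params()] object.
#' @return Non-negative signal, arbitrary units.
#' @examples
#' t <- tissue_presets("1.5T", "acute")$REMOTE_MYO
#' steady_state_signal(t, sequence_params("bright", "1.5T"))
#' steady_state_signal(t, sequence_params("dark", "1.5T"))
#' @export
steady_state_signal <- function(tissue, seq) {
  stopifnot(inherits(seq, "sequence_params"))
  if (tissue$T1 <= 0 || tissue$T2star <= 0) {
    stop("tissue T1 and T2* must be positive", call. = FALSE)
  }
  s <- tissue$PD * sin(deg2rad(seq$flip_angle)) *
    gre_saturation(tissue$T1, seq$RR, seq$flip_angle) *
    exp(-seq$TE / tissue$T2star)
  if (seq$prep == "dark") {
    s <- s * dir_recovery_fraction(tissue$T1, seq$TI, seq$eta_nonsel,
                                   seq$eta_sel, seq$kappa,
                                   flowing = isTRUE(tissue$flowing))
  }
  abs(s)
}

#' Per-class signal table
#'
#' @param tissues Named list of tissue entries (see [tissue_presets()]).
#' @param seq A [sequence_params()] object.
#' @return Named numeric vector of signals, one per tissue class.
#' @export
signal_table <- function(tissues, seq) {
  vapply(tissues, steady_state_signal, numeric(1), seq = seq)
}

# Map a label stack to intensities through a per-class lookup and apply
# Rician noise (magnitude of two independent Gaussian quadrature channels).
render_from_lut <- function(labels, lut_values, lut_codes, noise_sigma, seed) {
  idx <- match(as.vector(labels), lut_codes)
  if (anyNA(idx)) {
    stop("label map contains classes without tissue entries", call. = FALSE)
  }
  img <- array(lut_values[idx], dim = dim(labels))
  if (noise_sigma > 0) {
    img <- with_seed(seed, {
      n <- length(img)
      g1 <- stats::rnorm(n, 0, noise_sigma)
      g2 <- stats::rnorm(n, 0, noise_sigma)
      array(sqrt((as.vector(img) + g1)^2 + g2^2), dim = dim(img))
    })
  }
  img
}

#' Render a T2*-weighted magnitude image of the phantom
#'
#' Computes the noiseless per-class signal with [steady_state_signal()] and
#' applies Rician noise: each pixel is the magnitude of
#' `(signal + g1, g2)` with independent zero-mean Gaussians of SD
#' `seq$noise_sigma`. With `noise_sigma = 0` the image is piecewise
#' constant and equals the signal table exactly. Identical `seed` and
#' configuration give bit-identical output.
#'
#' @param label_map A [build_label_map()] result.
#' @param tissues Named tissue list covering every class present.
#' @param seq A [sequence_params()] object.
#' @param seed Integer RNG seed for the noise realization.
#' @return Object of class `sim_image`: `intensity` array plus `meta`.
#' @export
render_image <- function(label_map, tissues, seq, seed = NULL) {
  stopifnot(inherits(label_map, "label_map"), inherits(seq, "sequence_params"))
  lut <- signal_table(tissues, seq)
  codes <- TISSUE_CLASSES[names(lut)]
  if (anyNA(codes)) stop("unknown tissue class name in `tissues`", call. = FALSE)
  img <- render_from_lut(label_map$labels, lut, codes, seq$noise_sigma, seed)
  structure(list(intensity = img,
                 meta = list(modality = "T2sw", prep = seq$prep, seq = seq,
                             seed = seed,
                             pixel_spacing = label_map$geometry$pixel_spacing)),
            class = "sim_image")
}

#' Render a synthetic LGE image
#'
#' Piecewise-constant late-gadolinium-enhancement image (hyperintense
#' infarct including its hemorrhagic core, intermediate blood, remote
#' myocardium at `mu_remote`, air near zero) with Rician noise. Warns when
#' the configured MI mean sits below `mu_remote + 5 noise_sigma`, since the
#' mean + 5 SD infarct rule would then be unstable by construction.
#'
#' @param label_map A [build_label_map()] result.
#' @param contrast A [lge_contrast()] specification.
#' @param seed Integer RNG seed.
#' @return Object of class `sim_image` with modality `"LGE"`.
#' @export
render_lge <- function(label_map, contrast = lge_contrast(), seed = NULL) {
  stopifnot(inherits(label_map, "label_map"), inherits(contrast, "lge_contrast"))
  if (contrast$mu_mi < contrast$mu_remote + 5 * contrast$noise_sigma) {
    warning("LGE MI mean is below remote mean + 5 noise SD; ",
            "the infarct threshold rule will be unstable", call. = FALSE)
  }
  lut <- c(AIR = 0, BLOOD_FLOWING = contrast$mu_blood,
           BLOOD_STAGNANT = contrast$mu_blood,
           REMOTE_MYO = contrast$mu_remote,
           MI = contrast$mu_mi, IMH = contrast$mu_mi)
  img <- render_from_lut(label_map$labels, lut, TISSUE_CLASSES[names(lut)],
                         contrast$noise_sigma, seed)
  structure(list(intensity = img,
                 meta = list(modality = "LGE", contrast = contrast, seed = seed,
                             pixel_spacing = label_map$geometry$pixel_spacing)),
            class = "sim_image")
}
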