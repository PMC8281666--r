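#' AHA-style angular partition of a short-axis slice
#'
#' Divides the myocardium of each slice into `n_segments` equal angular
#' sectors counter-clockwise from `ref_angle` (6 segments for basal/mid
#' slices per the AHA recommendation, 4 for the apical variant). Pixel
#' assignment is deterministic by the polar angle of the pixel center;
#' segment `k` covers the half-open interval `((k-1) w, k w]` with
#' `w = 360 / n_segments`, so a pixel exactly on a sector boundary joins
#' the lower-indexed segment (angle 0 belongs to segment 1).
#'
#' @param myo_mask Logical myocardium mask (2D matrix or 3D stack; slices
#'   share the partition).
#' @param center LV center `(row, col)`, 0-based pixels; defaults to the
#'   myocardium centroid.
#' @param ref_angle Reference insertion angle, degrees.
#' @param n_segments 4 or 6.
#' @return Integer array of segment ids (0 outside the myocardium) with
#'   attributes `n_segments` and `ref_angle`.
#' @export
partition_slice <- function(myo_mask, center = NULL, ref_angle = 0,
                            n_segments = 6L) {
  if (!n_segments %in% c(4L, 6L)) {
    stop("`n_segments` must be 4 or 6", call. = FALSE)
  }
  myo <- as_intensity(myo_mask)
  dims <- dim(myo)
  myo2 <- if (length(dims) == 3) myo[, , 1, drop = TRUE] else myo
  storage.mode(myo2) <- "logical"
  if (!any(myo2)) stop("myocardium mask is empty", call. = FALSE)
  if (is.null(center)) {
    idx <- which(myo2, arr.ind = TRUE)
    center <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1) # 0-based
  }
  nr <- nrow(myo2); nc <- ncol(myo2)
  row0 <- matrix(0:(nr - 1), nr, nc)
  col0 <- t(matrix(0:(nc - 1), nc, nr))
  theta <- (atan2(-(row0 - center[1]), col0 - center[2]) * 180 / pi -
              ref_angle) %% 360
  w <- 360 / n_segments
  seg2 <- pmax(1L, as.integer(ceiling(theta / w)))
  seg2 <- pmin(seg2, n_segments)   # guard against theta numerically at 360
  seg2[!myo2] <- 0L
  seg <- if (length(dims) == 3) {
    array(seg2, dim = dims)
  } else {
    matrix(seg2, nr, nc)
  }
  attr(seg, "n_segments") <- n_segments
  attr(seg, "ref_angle") <- ref_angle
  seg
}

#' Per-segment myocardial and hypointense areas
#'
#' @param hypo_mask Logical hypointensity (detected IMH) stack, matching
#'   the partition dimensions.
#' @param partition Output of [partition_slice()].
#' @return `data.frame` with one row per slice x segment: `slice`,
#'   `segment`, `myo_area_px`, `hypo_area_px`,
#'   `hypo_fraction = hypo_area_px / myo_area_px`.
#' @export
segment_measurements <- function(hypo_mask, partition) {
  hypo <- check_mask(hypo_mask, dim(partition), "hypo_mask")
  n_seg <- attr(partition, "n_segments")
  dims <- dim(partition)
  n_slices <- if (length(dims) == 3) dims[3] else 1L
  part <- if (length(dims) == 3) partition else array(partition, c(dims, 1L))
  hyp <- if (length(dims) == 3) hypo else array(hypo, c(dims, 1L))
  out <- do.call(rbind, lapply(seq_len(n_slices), function(s) {
    p <- part[, , s]
    h <- hyp[, , s]
    myo_area <- tabulate(p[p > 0], nbins = n_seg)
    hypo_area <- tabulate(p[p > 0 & h], nbins = n_seg)
    data.frame(slice = s, segment = seq_len(n_seg),
               myo_area_px = myo_area, hypo_area_px = hypo_area,
               hypo_fraction = ifelse(myo_area > 0, hypo_area / myo_area, NA_real_))
  }))
  out[!is.na(out$hypo_fraction), , drop = FALSE]
}

#' Segment positivity calls by the 1% area rule
#'
#' A segment is positive for IMH when its hypointense area strictly
#' exceeds `positivity_threshold` (1% of the segment's cross-sectional
#' area by default; a fraction exactly at the threshold is negative).
#' Excluded segments (off-resonance-affected in practice) keep their
#' measurements but carry `excluded = TRUE` and are dropped from all
#' downstream counts.
#'
#' @param measurements A [segment_measurements()] data frame.
#' @param positivity_threshold Area fraction in (0, 1).
#' @param exclude Integer segment ids excluded on every slice, or a
#'   two-column data frame `(slice, segment)` for slice-specific exclusion.
#' @return The input with `positive` and `excluded` columns added.
#' @export
call_segments <- function(measurements, positivity_threshold = 0.01,
                          exclude = NULL) {
  if (positivity_threshold <= 0 || positivity_threshold >= 1) {
    stop("`positivity_threshold` must lie in (0, 1)", call. = FALSE)
  }
  m <- measurements
  m$positive <- m$hypo_fraction > positivity_threshold
  m$excluded <- FALSE
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) {
      key <- paste(m$slice, m$segment)
      m$excluded <- key %in% paste(exclude$slice, exclude$segment)
    } else {
      m$excluded <- m$segment %in% exclude
    }
  }
  m
}

#' Cross-tabulate test calls against reference calls
#'
#' @param calls_test,calls_ref [call_segments()] outputs over the same
#'   slice/segment set; a segment excluded in either arm is dropped from
#'   the table.
#' @return Object of class `contingency`: `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
contingency <- function(calls_test, calls_ref) {
  key_t <- paste(calls_test$slice, calls_test$segment)
  key_r <- paste(calls_ref$slice, calls_ref$segment)
  if (!identical(sort(key_t), sort(key_r))) {
    stop("test and reference cover different segment sets", call. = FALSE)
  }
  r <- calls_ref[match(key_t, key_r), ]
  keep <- !(calls_test$excluded | r$excluded)
  tt <- calls_test$positive[keep]
  rr <- r$positive[keep]
  structure(list(tp = sum(tt & rr), fp = sum(tt & !rr),
                 tn = sum(!tt & !rr), fn = sum(!tt & rr),
                 n = sum(keep)),
            class = "contingency")
}

#' Rank-sum (Mann-Whitney) AUC with midrank ties
#'
#' Area under the ROC curve of a continuous score against binary labels,
#' computed from the rank-sum statistic with midranks for ties; identical
#' to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical reference labels.
#' @return AUC in [0, 1]; `NA` when either class is absent.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-subject diagnostic summary
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n` (true positives and true negatives over all segments
#' evaluated), and — when the continuous per-segment hypointense fractions
#' of the test arm are supplied — the rank-sum AUC against the binary
#' reference calls. Quantities whose denominator is empty (e.g.
#' sensitivity with no reference positives) are returned as `NA`, never
#' silently 0.
#'
#' @param ct A [contingency()] object.
#' @param test_fractions Optional numeric vector of test-arm hypointense
#'   fractions for the evaluated (non-excluded) segments.
#' @param ref_calls Optional logical reference calls matching
#'   `test_fractions`.
#' @return Object of class `dx_summary`: `sensitivity`, `specificity`,
#'   `accuracy`, `auc`.
#' @export
dx_summary <- function(ct, test_fractions = NULL, ref_calls = NULL) {
  stopifnot(inherits(ct, "contingency"))
  if (ct$n == 0) stop("no segments evaluated", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  auc <- if (!is.null(test_fractions) && !is.null(ref_calls)) {
    auc_rank(test_fractions, ref_calls)
  } else {
    NA_real_
  }
  structure(list(sensitivity = safe_div(ct$tp, ct$tp + ct$fn),
                 specificity = safe_div(ct$tn, ct$tn + ct$fp),
                 accuracy = (ct$tp + ct$tn) / ct$n,
                 auc = auc),
            class = "dx_summary")
}

#' @export
print.dx_summary <- function(x, ...) {
  cat(sprintf("sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %s\n",
              x$sensitivity, x$specificity, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Segmental diagnostics of one arm against another
#'
#' Full segmental chain for a subject: partition every slice, measure
#' hypointense fractions of the test and reference IMH masks, call
#' segments by the 1% rule, cross-tabulate and summarize. Used with the
#' dark arm as test and the bright arm as reference ground truth.
#'
#' @param subject A [simulate_subject()] result (provides geometry).
#' @param test_mask,ref_mask Logical detected-IMH stacks.
#' @param positivity_threshold Area-fraction threshold.
#' @param exclude Segment exclusion spec (see [call_segments()]).
#' @param n_segments Segments per slice.
#' @return List: `summary` ([dx_summary()]), `contingency`, `calls_test`,
#'   `calls_ref`.
#' @export
subject_dx <- function(subject, test_mask, ref_mask,
                       positivity_threshold = 0.01, exclude = NULL,
                       n_segments = 6L) {
  stopifnot(inherits(subject, "sim_subject"))
  geom <- subject$label_map$geometry
  part <- partition_slice(subject$truth$masks$lv_myo,
                          center = geom$lv_center,
                          ref_angle = geom$ref_insertion_angle,
                          n_segments = n_segments)
  m_test <- call_segments(segment_measurements(test_mask, part),
                          positivity_threshold, exclude)
  m_ref <- call_segments(segment_measurements(ref_mask, part),
                         positivity_threshold, exclude)
  ct <- contingency(m_test, m_ref)
  keep <- !(m_test$excluded | m_ref$excluded)
  list(summary = dx_summary(ct, m_test$hypo_fraction[keep],
                            m_ref$positive[keep]),
       contingency = ct, calls_test = m_test, calls_ref = m_ref)
}
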