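#' Compute the seven periocular measurements
#'
#' Converts a landmark set to millimetre metrics using a calibration scale.
#' MRD1 and MRD2 are signed vertical (y-axis) distances: MRD1 is positive
#' when the upper-lid midpoint lies above the pupillary centre, and a
#' negative MRD1 (lid at or below the pupil centre, as in severe ptosis) is
#' reported, not rejected. PFH is MRD1 + MRD2 by construction. IPD, IICD,
#' OICD and HPA are full Euclidean distances between the named landmarks,
#' which makes them invariant to in-plane head roll; the vertical MRDs are
#' not (set `euclidean_horizontal = FALSE` to use x-axis components
#' instead).
#'
#' @param landmarks A [landmark_set()].
#' @param scale A [calibration_scale()] (or a positive mm-per-px scalar).
#' @param euclidean_horizontal Use Euclidean distance (default) rather than
#'   the horizontal component for IPD/IICD/OICD/HPA.
#' @return A one-row data frame of class `measurement_record` with columns
#'   `mrd1_right`, `mrd1_left`, `mrd2_right`, `mrd2_left`, `pfh_right`,
#'   `pfh_left`, `hpa_right`, `hpa_left`, `ipd`, `iicd`, `oicd` (mm) and
#'   `mm_per_px`.
#' @export
compute_measurements <- function(landmarks, scale,
                                 euclidean_horizontal = TRUE) {
  lm <- landmark_set(landmarks, strict = FALSE)
  mmpp <- if (inherits(scale, "calibration_scale")) scale$mm_per_px
          else as.numeric(scale)
  if (!(mmpp > 0)) stop("mm_per_px must be positive")
  dist_fun <- if (euclidean_horizontal)
    function(a, b) sqrt(sum((lm[a, ] - lm[b, ])^2))
  else
    function(a, b) abs(lm[a, "x"] - lm[b, "x"])

  mrd1_r <- (lm[1, "y"] - lm[2, "y"]) * mmpp
  mrd2_r <- (lm[3, "y"] - lm[1, "y"]) * mmpp
  mrd1_l <- (lm[6, "y"] - lm[7, "y"]) * mmpp
  mrd2_l <- (lm[8, "y"] - lm[6, "y"]) * mmpp
  rec <- data.frame(
    mrd1_right = mrd1_r, mrd1_left = mrd1_l,
    mrd2_right = mrd2_r, mrd2_left = mrd2_l,
    pfh_right = mrd1_r + mrd2_r, pfh_left = mrd1_l + mrd2_l,
    hpa_right = dist_fun(4, 5) * mmpp,
    hpa_left = dist_fun(9, 10) * mmpp,
    ipd = dist_fun(1, 6) * mmpp,
    iicd = dist_fun(4, 9) * mmpp,
    oicd = dist_fun(5, 10) * mmpp,
    mm_per_px = mmpp,
    row.names = NULL)
  class(rec) <- c("measurement_record", "data.frame")
  rec
}

measurement_metrics <- function() {
  list(bilateral = c("mrd1", "mrd2", "pfh", "hpa"),
       central = c("ipd", "iicd", "oicd"))
}

#' @export
print.measurement_record <- function(x, ...) {
  cat("Periocular measurements (mm):\n")
  m <- measurement_metrics()
  for (f in m$bilateral)
    cat(sprintf("  %-5s R %6.2f  L %6.2f\n", toupper(f),
                x[[paste0(f, "_right")]], x[[paste0(f, "_left")]]))
  for (f in m$central)
    cat(sprintf("  %-5s %8.2f\n", toupper(f), x[[f]]))
  cat(sprintf("  scale %.5f mm/px\n", x$mm_per_px))
  invisible(x)
}

#' Measure an image end-to-end
#'
#' Runs the full pipeline on one photograph: detect the fiducial sticker,
#' derive the pixel-to-millimetre scale, predict the ten landmarks with a
#' trained detector, and compute the seven measurements. The returned record
#' carries the landmarks, fitted circle and scale as attributes for audit.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param model A trained [train_detector()] model, or `NULL` to use
#'   `landmarks` directly.
#' @param sticker_diameter_mm Physical fiducial diameter, mm.
#' @param landmarks Optional known landmark set (bypasses the detector).
#' @return A `measurement_record` with attributes `landmarks`, `circle`, and
#'   `scale`.
#' @export
measure_image <- function(image, model = NULL, sticker_diameter_mm = 24,
                          landmarks = NULL) {
  scale <- calibrate_image(image, diameter_mm = sticker_diameter_mm)
  if (is.null(landmarks)) {
    if (is.null(model)) stop("either a trained model or landmarks are required")
    landmarks <- predict(model, image)
  }
  rec <- compute_measurements(landmarks, scale)
  attr(rec, "landmarks") <- landmarks
  attr(rec, "circle") <- scale$circle
  attr(rec, "scale") <- scale
  rec
}
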