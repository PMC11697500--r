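#' Calibration scale
#'
#' Conversion factor between image pixels and millimetres, optionally with
#' the fitted fiducial circle it was derived from.
#'
#' @param mm_per_px Scale, mm per pixel (> 0).
#' @param circle Optional list `(centre = c(x, y), radius = r)` in pixels.
#' @param diameter_mm Physical fiducial diameter, mm.
#' @param fit_residual RMS residual of the circle fit, px.
#' @return A list of class `calibration_scale`.
#' @export
calibration_scale <- function(mm_per_px, circle = NULL, diameter_mm = 24,
                              fit_residual = NA_real_) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 || !(mm_per_px > 0))
    stop("mm_per_px must be a positive scalar")
  structure(list(mm_per_px = mm_per_px, circle = circle,
                 diameter_mm = diameter_mm, fit_residual = fit_residual),
            class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("Calibration: %.5f mm/px (fiducial %.1f mm", x$mm_per_px,
              x$diameter_mm))
  if (!is.null(x$circle))
    cat(sprintf(", fitted radius %.2f px, RMS residual %.3f px",
                x$circle$radius, x$fit_residual))
  cat(")\n")
  invisible(x)
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit of a circle to 2D points, minimising the residuals of
#' \eqn{x^2 + y^2 - 2ax - 2by - c}.
#'
#' @param pts n x 2 matrix of (x, y) points, n >= 3.
#' @return List with `centre` (x, y), `radius`, and `residual` (RMS of the
#'   radial distances minus the fitted radius).
#' @export
fit_circle <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("need at least 3 points to fit a circle")
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- qr.solve(A, b)
  centre <- sol[1:2]
  radius <- sqrt(sol[3] + sum(centre^2))
  d <- sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
  list(centre = unname(centre), radius = unname(radius),
       residual = sqrt(mean((d - radius)^2)))
}

# Greenness mask: dominant green channel with a margin over red/blue.
green_mask <- function(image, min_green = 0.30, margin = 0.12) {
  image[, , 2] > min_green &
    (image[, , 2] - pmax(image[, , 1], image[, , 3])) > margin
}

#' Detect the green fiducial sticker
#'
#' Thresholds green pixels, labels connected components, keeps components
#' with sufficient area and circularity \eqn{4\pi A / P^2 \ge 0.8} (perimeter
#' estimated from boundary crossings with the Cauchy-Crofton \eqn{\pi/4}
#' correction, so an ideal disc scores ~1), picks the largest, and fits a
#' least-squares circle to its boundary pixels.
#'
#' @param image H x W x 3 array, values in `[0, 1]`.
#' @param min_area Minimum component area in px.
#' @param min_circularity Minimum circularity to qualify.
#' @return List `(centre, radius, residual, degraded)`; `degraded` is TRUE
#'   when the RMS residual exceeds 10% of the radius.
#' @export
detect_sticker <- function(image, min_area = 50, min_circularity = 0.8) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("detect_sticker expects an H x W x 3 RGB array")
  mask <- green_mask(image)
  if (!any(mask)) stop("calibration-not-found: no green pixels in image")
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  areas <- tabulate(lab[lab > 0])
  best <- 0L; best_area <- -Inf
  for (k in which(areas >= min_area)) {
    comp <- lab == k
    circ <- component_circularity(comp)
    if (circ >= min_circularity && areas[k] > best_area) {
      best <- k; best_area <- areas[k]
    }
  }
  if (best == 0L)
    stop("calibration-not-found: no green component of area >= ", min_area,
         " with circularity >= ", min_circularity)
  comp <- lab == best
  bnd <- boundary_pixels(comp)
  fit <- fit_circle(bnd)
  fit$degraded <- fit$residual > 0.1 * fit$radius
  if (fit$degraded)
    warning("degraded fiducial fit: RMS residual ", signif(fit$residual, 3),
            " px exceeds 10% of radius")
  fit
}

# 0-based (x, y) centres of component pixels having a 4-neighbour outside
boundary_pixels <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- comp
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
           pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  idx <- which(comp & !inner, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

component_circularity <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- comp
  crossings <- sum(pad[1:(h + 1), ] != pad[2:(h + 2), ]) +
               sum(pad[, 1:(w + 1)] != pad[, 2:(w + 2)])
  P <- crossings * pi / 4
  A <- sum(comp)
  4 * pi * A / P^2
}

#' Convert a fitted fiducial circle to a calibration scale
#'
#' The physical diameter divided by the fitted pixel diameter gives the
#' mm-per-pixel factor.
#'
#' @param circle List with `radius` (px) and optionally `centre`, `residual`.
#' @param diameter_mm Physical diameter of the fiducial dot, mm (default 24).
#' @return A [calibration_scale()].
#' @export
scale_from_circle <- function(circle, diameter_mm = 24) {
  if (!is.numeric(circle$radius) || !(circle$radius > 0))
    stop("circle radius must be positive")
  calibration_scale(mm_per_px = diameter_mm / (2 * circle$radius),
                    circle = circle, diameter_mm = diameter_mm,
                    fit_residual = if (is.null(circle$residual)) NA_real_
                                   else circle$residual)
}

#' Calibrate an image from its fiducial sticker
#'
#' Convenience composition of [detect_sticker()] and [scale_from_circle()].
#'
#' @inheritParams detect_sticker
#' @inheritParams scale_from_circle
#' @return A [calibration_scale()].
#' @export
calibrate_image <- function(image, diameter_mm = 24, min_area = 50,
                            min_circularity = 0.8) {
  scale_from_circle(detect_sticker(image, min_area, min_circularity),
                    diameter_mm)
}
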