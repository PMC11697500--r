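#' Canonical periocular landmark names
#'
#' The ten landmarks used throughout the package, in fixed index order:
#' pupillary centre, upper eyelid margin midpoint, lower eyelid margin
#' midpoint, medial canthus and lateral canthus — first for the subject's
#' right eye (indices 1-5), then the left eye (indices 6-10). "Right" and
#' "left" are the subject's sides; in a head-on photograph the subject's
#' right eye appears on the left of the image.
#'
#' @return Character vector of length 10.
#' @export
landmark_names <- function() {
  roles <- c("pupil_centre", "upper_lid_mid", "lower_lid_mid",
             "medial_canthus", "lateral_canthus")
  c(paste0(roles, "_r"), paste0(roles, "_l"))
}

# Index permutation applied when an image is mirrored horizontally: the two
# eye blocks swap wholesale, each role mapping to the same role on the other
# side (pupil<->pupil, medial<->medial, ...).
flip_permutation <- function() c(6:10, 1:5)

#' Construct a landmark set
#'
#' A landmark set is a 10 x 2 numeric matrix of sub-pixel image coordinates
#' with columns `x`, `y` and rows named by [landmark_names()]. Coordinates
#' are 0-based with the origin at the centre of the top-left pixel, x
#' rightward and y downward.
#'
#' @param xy Numeric 10 x 2 matrix (or object coercible to one), ordered as
#'   [landmark_names()].
#' @param strict Enforce the lid-ordering invariant (upper-lid midpoint above
#'   the lower, i.e. smaller y) as an error; with `strict = FALSE` a
#'   violation — possible in raw detector output — is only a warning.
#' @return A validated landmark matrix.
#' @export
landmark_set <- function(xy, strict = TRUE) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (!identical(dim(xy), c(10L, 2L)))
    stop("a landmark set must be a 10 x 2 matrix, got ",
         paste(dim(xy), collapse = " x "))
  if (!all(is.finite(xy)))
    stop("landmark coordinates must all be finite")
  dimnames(xy) <- list(landmark_names(), c("x", "y"))
  for (eye in c(0L, 5L)) {
    if (!(xy[eye + 2L, "y"] < xy[eye + 3L, "y"])) {
      msg <- paste0("upper-lid midpoint does not lie above the lower-lid ",
                    "midpoint for the ", if (eye == 0L) "right" else "left",
                    " eye")
      if (strict) stop(msg) else warning(msg)
    }
  }
  xy
}

validate_landmarks_in_bounds <- function(lm, width, height) {
  bad <- which(lm[, "x"] < 0 | lm[, "x"] > width - 1 |
               lm[, "y"] < 0 | lm[, "y"] > height - 1)
  if (length(bad))
    stop("landmark(s) outside image bounds: ",
         paste(rownames(lm)[bad], collapse = ", "))
  invisible(lm)
}

# ---- affine helpers (2 x 3 matrices acting on 0-based pixel-centre coords) --

affine_identity <- function() cbind(diag(2), c(0, 0))

# rotation (degrees, image convention: positive rotates the +x axis toward
# +y, i.e. clockwise on screen) and isotropic scale about a centre point
affine_rot_scale <- function(deg, scale, centre) {
  th <- deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cbind(R, centre - R %*% centre)
}

# anisotropic resize mapping a (w, h) raster onto (out_w, out_h), aligned on
# pixel centres: x' = (x + 0.5) * out_w / w - 0.5
affine_resize <- function(w, h, out_w, out_h) {
  sx <- out_w / w
  sy <- out_h / h
  cbind(diag(c(sx, sy)), c(0.5 * sx - 0.5, 0.5 * sy - 0.5))
}

affine_flip_x <- function(w) cbind(diag(c(-1, 1)), c(w - 1, 0))

affine_compose <- function(a, b) {  # returns a %*% b as maps: (a o b)(x)
  cbind(a[, 1:2] %*% b[, 1:2], a[, 1:2] %*% b[, 3] + a[, 3])
}

affine_invert <- function(m) {
  Ri <- solve(m[, 1:2])
  cbind(Ri, -Ri %*% m[, 3])
}

affine_apply <- function(m, pts) {
  pts <- as.matrix(pts)
  out <- t(m[, 1:2] %*% t(pts) + m[, 3])
  dimnames(out) <- dimnames(pts)
  out
}

# warp an H x W x C image by the affine `m` (input -> output coordinates)
warp_image <- function(img, m, out_w, out_h, fill = NULL) {
  minv <- affine_invert(m)
  clamp <- is.null(fill)
  if (clamp) fill <- numeric(dim(img)[3])
  .affine_warp(img, minv, as.integer(out_h), as.integer(out_w),
               as.numeric(fill), clamp)
}
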