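#' Augment an image/landmark pair
#'
#' Draws one random affine (in-plane rotation about the image centre and
#' isotropic scaling) and, with probability `flip_prob`, a horizontal flip,
#' and applies it identically to the raster and the landmarks. A flip maps
#' `x -> w - 1 - x` and swaps the right-eye landmark block (indices 1-5)
#' with the left-eye block (6-10), so each role keeps its anatomical meaning.
#' If any transformed landmark leaves the frame, the affine is re-drawn up to
#' `max_tries` times; after that the sample is returned unaugmented with
#' attribute `augmented = FALSE`.
#'
#' @param image H x W x C array.
#' @param landmarks A [landmark_set()].
#' @param rotation Max absolute rotation, degrees (drawn uniformly).
#' @param scale Length-2 range of isotropic scale factors.
#' @param flip_prob Probability of a horizontal flip.
#' @param max_tries Re-draws before giving up.
#' @return List `(image, landmarks)` with logical attribute `augmented`.
#' @export
augment_sample <- function(image, landmarks, rotation = 30,
                           scale = c(0.75, 1.25), flip_prob = 0.5,
                           max_tries = 5) {
  h <- dim(image)[1]; w <- dim(image)[2]
  lm <- landmark_set(landmarks)
  centre <- c((w - 1) / 2, (h - 1) / 2)
  for (i in seq_len(max_tries)) {
    deg <- runif(1, -rotation, rotation)
    sc <- runif(1, scale[1], scale[2])
    flip <- runif(1) < flip_prob
    M <- affine_rot_scale(deg, sc, centre)
    if (flip) M <- affine_compose(affine_flip_x(w), M)
    new_lm <- affine_apply(M, lm)
    if (flip) new_lm <- new_lm[flip_permutation(), , drop = FALSE]
    inb <- all(new_lm[, 1] >= 0 & new_lm[, 1] <= w - 1 &
               new_lm[, 2] >= 0 & new_lm[, 2] <= h - 1)
    if (inb) {
      out <- list(image = warp_image(image, M, w, h),
                  landmarks = landmark_set(new_lm))
      attr(out, "augmented") <- TRUE
      attr(out, "transform") <- M
      return(out)
    }
  }
  out <- list(image = image, landmarks = lm)
  attr(out, "augmented") <- FALSE
  out
}
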