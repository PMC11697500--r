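#' Default scene parameter ranges
#'
#' Ranges used by [sample_scene_params()] to draw the geometry of a synthetic
#' periocular scene. Millimetre metrics are drawn from normal distributions
#' truncated at `trunc_sd` standard deviations, with population means and SDs
#' matching adult clinic values (MRD1 3.66 (0.89) mm, MRD2 5.24 (1.22) mm,
#' HPA 25.30 (2.08) mm, IPD 61.2 (3.7) mm, IICD 33.3 (3.4) mm). The outer
#' intercanthal distance is derived as IICD + HPA_right + HPA_left so the
#' horizontal layout is self-consistent. `mm_per_px` (camera standoff /
#' zoom variation) and head roll are drawn uniformly / truncated-normally.
#'
#' @param ... Named overrides for any element of the returned list.
#' @return A list of range specifications.
#' @export
scene_ranges <- function(...) {
  r <- list(
    mrd1        = c(mean = 3.66, sd = 0.89),
    mrd2        = c(mean = 5.24, sd = 1.22),
    hpa         = c(mean = 25.30, sd = 2.08),
    ipd         = c(mean = 61.2, sd = 3.7),
    iicd        = c(mean = 33.3, sd = 3.4),
    mm_per_px   = c(min = 0.21, max = 0.25),
    head_roll   = c(sd = 2, max = 5),
    noise_sd    = 0.02,
    sticker_diameter_mm = 24,
    image_size  = c(512L, 256L),
    trunc_sd    = 2
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(r))
    if (length(unknown)) stop("unknown range field(s): ",
                              paste(unknown, collapse = ", "))
    r[names(dots)] <- dots
  }
  r
}

rtruncnorm1 <- function(mean, sd, trunc) {
  if (sd < 0) stop("negative SD in parameter range")
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1, mean, sd)
    if (abs(x - mean) <= trunc * sd) return(x)
  }
}

validate_ranges <- function(ranges) {
  for (f in c("mrd1", "mrd2", "hpa", "ipd", "iicd")) {
    v <- ranges[[f]]
    if (v[["mean"]] - ranges$trunc_sd * v[["sd"]] <= 0)
      stop("infeasible range for ", f, ": lower truncation bound must stay positive")
  }
  mp <- ranges$mm_per_px
  if (mp[["min"]] <= 0 || mp[["max"]] < mp[["min"]])
    stop("infeasible mm_per_px range")
  invisible(ranges)
}

#' Draw scene parameters
#'
#' Draws one set of scene parameters from `ranges`, reproducibly for a given
#' seed. Bilateral metrics (MRD1, MRD2, HPA) are drawn independently per
#' side; OICD is derived from IICD and the two HPAs.
#'
#' @param rng_seed Integer seed; identical seeds yield identical parameters.
#' @param ranges A range list from [scene_ranges()].
#' @return A `scene_params` list; see [scene_params()].
#' @export
sample_scene_params <- function(rng_seed, ranges = scene_ranges()) {
  validate_ranges(ranges)
  set.seed(rng_seed)
  tr <- ranges$trunc_sd
  draw <- function(f) rtruncnorm1(ranges[[f]][["mean"]], ranges[[f]][["sd"]], tr)
  w <- ranges$image_size[1]
  h <- ranges$image_size[2]
  iicd <- draw("iicd")
  hpa_r <- draw("hpa")
  hpa_l <- draw("hpa")
  mp <- runif(1, ranges$mm_per_px[["min"]], ranges$mm_per_px[["max"]])
  roll <- rtruncnorm1(0, ranges$head_roll[["sd"]],
                      ranges$head_roll[["max"]] / max(ranges$head_roll[["sd"]], 1e-12))
  scene_params(
    mrd1_right = draw("mrd1"), mrd1_left = draw("mrd1"),
    mrd2_right = draw("mrd2"), mrd2_left = draw("mrd2"),
    hpa_right = hpa_r, hpa_left = hpa_l,
    ipd = draw("ipd"), iicd = iicd, oicd = iicd + hpa_r + hpa_l,
    mm_per_px_true = mp,
    sticker_diameter_mm = ranges$sticker_diameter_mm,
    sticker_center = c((w - 1) / 2 + runif(1, -8, 8) * w / 512,
                       0.26 * h + runif(1, -4, 4) * h / 256),
    head_roll_deg = roll,
    noise_sd = ranges$noise_sd,
    image_size = c(w, h)
  )
}

#' Scene parameters for a synthetic periocular image
#'
#' Ground-truth description of one schematic face: the seven millimetre
#' metrics (bilateral ones per side), the true scale, the fiducial sticker
#' geometry, in-plane head roll and pixel noise level.
#'
#' @param mrd1_right,mrd1_left,mrd2_right,mrd2_left Marginal reflex
#'   distances, mm (> 0).
#' @param hpa_right,hpa_left Horizontal palpebral apertures, mm (> 0).
#' @param ipd,iicd,oicd Interpupillary and inner/outer intercanthal
#'   distances, mm; `oicd` must equal `iicd + hpa_right + hpa_left` within
#'   0.5 mm.
#' @param mm_per_px_true True scale, mm per pixel (> 0).
#' @param sticker_diameter_mm Fiducial dot diameter, mm (default 24).
#' @param sticker_center Pixel coordinates (x, y) of the dot centre.
#' @param head_roll_deg In-plane roll applied to the whole scene, degrees.
#' @param noise_sd Gaussian pixel noise SD on intensities in `[0, 1]`.
#' @param image_size Raster size `c(width, height)` in pixels.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(mrd1_right, mrd1_left, mrd2_right, mrd2_left,
                         hpa_right, hpa_left, ipd, iicd, oicd,
                         mm_per_px_true,
                         sticker_diameter_mm = 24,
                         sticker_center = NULL,
                         head_roll_deg = 0,
                         noise_sd = 0.02,
                         image_size = c(512L, 256L)) {
  if (is.null(sticker_center))
    sticker_center <- c((image_size[1] - 1) / 2, 0.26 * image_size[2])
  p <- list(mrd1_right = mrd1_right, mrd1_left = mrd1_left,
            mrd2_right = mrd2_right, mrd2_left = mrd2_left,
            hpa_right = hpa_right, hpa_left = hpa_left,
            ipd = ipd, iicd = iicd, oicd = oicd,
            mm_per_px_true = mm_per_px_true,
            sticker_diameter_mm = sticker_diameter_mm,
            sticker_center = as.numeric(sticker_center),
            head_roll_deg = head_roll_deg,
            noise_sd = noise_sd,
            image_size = as.integer(image_size))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  mm_fields <- c("mrd1_right", "mrd1_left", "mrd2_right", "mrd2_left",
                 "hpa_right", "hpa_left", "ipd", "iicd", "oicd",
                 "mm_per_px_true", "sticker_diameter_mm")
  for (f in mm_fields)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !(p[[f]] > 0))
      stop("scene parameter '", f, "' must be a positive scalar")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(p$oicd > p$iicd)) stop("oicd must exceed iicd")
  if (abs(p$iicd + p$hpa_right + p$hpa_left - p$oicd) > 0.5)
    stop("layout inconsistency: iicd + hpa_right + hpa_left must equal oicd ",
         "within 0.5 mm")
  if (any(p$image_size < 32)) stop("image_size too small")
  invisible(p)
}

# ---- rendering primitives ---------------------------------------------------

SKIN <- c(0.86, 0.72, 0.62)
SCLERA <- c(0.97, 0.96, 0.95)
IRIS <- c(0.35, 0.25, 0.15)
PUPIL <- c(0.05, 0.05, 0.05)
LIDLINE <- c(0.30, 0.18, 0.12)
STICKER_GREEN <- c(0.10, 0.65, 0.20)

# blend `col` into img over an anti-aliased disc; `clip` optionally limits
# coverage (same window). Window coordinates are 0-based pixel centres.
blend_window <- function(img, rows, cols, cov, col) {
  for (ch in 1:3)
    img[rows, cols, ch] <- img[rows, cols, ch] * (1 - cov) + col[ch] * cov
  img
}

disc_window <- function(img, cx, cy, r) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r) + 2)   # 1-based
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r) + 2)
  d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+"))
  list(rows = rows, cols = cols, cov = pmin(pmax(r + 0.5 - d, 0), 1))
}

draw_disc <- function(img, cx, cy, r, col, clip = NULL) {
  dw <- disc_window(img, cx, cy, r)
  cov <- dw$cov
  if (!is.null(clip)) cov <- cov * clip(dw$rows, dw$cols)
  blend_window(img, dw$rows, dw$cols, cov, col)
}

# quadratic y(x) through three points
parabola_through <- function(x, y) {
  solve(cbind(x^2, x, 1), y)
}

eval_quad <- function(coef, x) coef[1] * x^2 + coef[2] * x + coef[3]

# draw one schematic eye; all coordinates 0-based pixel centres.
# Returns updated image.
draw_eye <- function(img, pupil, upper, lower, medial, lateral, mmpp) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cu <- parabola_through(c(medial[1], upper[1], lateral[1]),
                         c(medial[2], upper[2], lateral[2]))
  cl <- parabola_through(c(medial[1], lower[1], lateral[1]),
                         c(medial[2], lower[2], lateral[2]))
  x0 <- min(medial[1], lateral[1]); x1 <- max(medial[1], lateral[1])
  cols <- max(1, floor(x0) + 1):min(w, ceiling(x1) + 1)      # 1-based
  xs <- cols - 1
  u <- eval_quad(cu, xs); l <- eval_quad(cl, xs)
  rows <- max(1, floor(min(u)) - 1):min(h, ceiling(max(l)) + 3)
  ys <- rows - 1
  Y <- matrix(ys, length(ys), length(xs))
  U <- matrix(u, length(ys), length(xs), byrow = TRUE)
  L <- matrix(l, length(ys), length(xs), byrow = TRUE)
  # aperture coverage: inside the region between the two lid arcs
  cov <- pmin(pmax(Y - U + 0.5, 0), 1) * pmin(pmax(L - Y + 0.5, 0), 1)
  # taper to zero at the canthi so the aperture closes cleanly
  tap <- pmin(pmax((xs - x0 + 0.5), 0), 1) * pmin(pmax((x1 - xs + 0.5), 0), 1)
  cov <- cov * matrix(tap, length(ys), length(xs), byrow = TRUE)
  img <- blend_window(img, rows, cols, cov, SCLERA)
  clipfun <- function(rr, cc) {
    ri <- match(rr, rows); ci <- match(cc, cols)
    out <- matrix(0, length(rr), length(cc))
    ok_r <- !is.na(ri); ok_c <- !is.na(ci)
    out[ok_r, ok_c] <- cov[ri[ok_r], ci[ok_c], drop = FALSE]
    out
  }
  img <- draw_disc(img, pupil[1], pupil[2], 5.5 / mmpp, IRIS, clip = clipfun)
  img <- draw_disc(img, pupil[1], pupil[2], 2.0 / mmpp, PUPIL, clip = clipfun)
  # lid margin lines (eyelash/lid-crease contrast)
  for (arc in list(U, L)) {
    line_cov <- pmax(0, 1 - abs(Y - arc)) * 0.85
    img <- blend_window(img, rows, cols, line_cov, LIDLINE)
  }
  img
}

#' Render a synthetic periocular scene
#'
#' Draws a schematic frontal face fragment — two eyes (white aperture bounded
#' by parabolic lid arcs, iris and pupil discs, dark lid margins) and a green
#' circular fiducial dot — on a skin-toned background. Ground-truth landmark
#' coordinates are placed analytically from the millimetre parameters, the
#' whole scene (raster and coordinates alike) is then rotated by
#' `head_roll_deg` about the image centre, and Gaussian pixel noise is added.
#' The noise draw uses the current RNG state.
#'
#' @param params A [scene_params()] object.
#' @return A `synthetic_sample` list with elements `image` (H x W x 3 array
#'   in `[0, 1]`), `landmarks_true` ([landmark_set()]), `sticker_circle_true`
#'   (list `centre`, `radius` in px), `params`, and `measurements_true`
#'   (the metrics recomputed from the true landmarks at the true scale).
#' @export
render_scene <- function(params) {
  validate_scene_params(params)
  w <- params$image_size[1]; h <- params$image_size[2]
  mmpp <- params$mm_per_px_true
  px <- function(mm) mm / mmpp
  cx <- (w - 1) / 2
  eye_y <- 0.72 * (h - 1)

  lm <- matrix(NA_real_, 10, 2)
  for (side in c("right", "left")) {
    s <- if (side == "right") -1 else 1       # subject's right on image left
    off <- if (side == "right") 0L else 5L
    pupil <- c(cx + s * px(params$ipd) / 2, eye_y)
    medial <- c(cx + s * px(params$iicd) / 2, eye_y)
    lateral <- c(medial[1] + s * px(params[[paste0("hpa_", side)]]), eye_y)
    upper <- c(pupil[1], eye_y - px(params[[paste0("mrd1_", side)]]))
    lower <- c(pupil[1], eye_y + px(params[[paste0("mrd2_", side)]]))
    lm[off + 1:5, ] <- rbind(pupil, upper, lower, medial, lateral)
  }

  # bounds are validated on the post-roll geometry, before rasterising
  centre <- c((w - 1) / 2, (h - 1) / 2)
  roll_M <- affine_rot_scale(params$head_roll_deg, 1, centre)
  lm_rolled <- affine_apply(roll_M, lm)
  sticker_rolled <- drop(affine_apply(roll_M, matrix(params$sticker_center, 1)))
  r_sticker <- px(params$sticker_diameter_mm) / 2
  margin <- 2
  ok <- function(pt, r = 0) all(pt[1] - r >= margin, pt[1] + r <= w - 1 - margin,
                                pt[2] - r >= margin, pt[2] + r <= h - 1 - margin)
  if (!all(apply(lm_rolled, 1, ok)) || !ok(sticker_rolled, r_sticker))
    stop("scene geometry exceeds image bounds; enlarge image_size or ",
         "increase mm_per_px_true")

  img <- array(rep(SKIN, each = h * w), dim = c(h, w, 3))
  for (off in c(0L, 5L))
    img <- draw_eye(img, lm[off + 1, ], lm[off + 2, ], lm[off + 3, ],
                    lm[off + 4, ], lm[off + 5, ], mmpp)
  img <- draw_disc(img, params$sticker_center[1], params$sticker_center[2],
                   r_sticker, STICKER_GREEN)

  if (params$head_roll_deg != 0)
    img <- warp_image(img, roll_M, w, h, fill = SKIN)
  lm <- lm_rolled
  sticker_c <- sticker_rolled

  if (params$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, params$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)

  lm <- landmark_set(lm)
  sample <- list(image = img,
                 landmarks_true = lm,
                 sticker_circle_true = list(centre = sticker_c, radius = r_sticker),
                 params = params,
                 measurements_true = compute_measurements(
                   lm, calibration_scale(mm_per_px = mmpp)))
  class(sample) <- "synthetic_sample"
  sample
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n` scenes with per-sample seeds derived deterministically from
#' `seed`, so the same call always yields identical samples.
#'
#' @param n Number of scenes (>= 1).
#' @param seed Master seed.
#' @param ranges Parameter ranges; see [scene_ranges()].
#' @return A list of `synthetic_sample` objects of class `scene_dataset`,
#'   with a `manifest` attribute (data frame of true values per sample).
#' @export
make_dataset <- function(n, seed, ranges = scene_ranges()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sample_scene_params(sample_seeds[i], ranges)
    samples[[i]] <- render_scene(p)
    samples[[i]]$id <- sprintf("scene_%04d", i)
    samples[[i]]$seed <- sample_seeds[i]
  }
  manifest <- do.call(rbind, lapply(samples, function(s) {
    data.frame(id = s$id, seed = s$seed,
               as.data.frame(s$params[c("mrd1_right", "mrd1_left",
                                        "mrd2_right", "mrd2_left",
                                        "hpa_right", "hpa_left",
                                        "ipd", "iicd", "oicd",
                                        "mm_per_px_true", "head_roll_deg")]))
  }))
  attr(samples, "manifest") <- manifest
  attr(samples, "seed") <- seed
  class(samples) <- "scene_dataset"
  samples
}

#' @export
print.synthetic_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic periocular scene %s: %d x %d px, %.3f mm/px, roll %.2f deg\n",
              if (!is.null(x$id)) x$id else "", d[2], d[1],
              x$params$mm_per_px_true, x$params$head_roll_deg))
  invisible(x)
}

#' Display a synthetic scene with its ground-truth landmarks
#'
#' @param x A `synthetic_sample`.
#' @param landmarks Logical; overlay the true landmarks.
#' @param ... Unused.
#' @export
plot.synthetic_sample <- function(x, landmarks = TRUE, ...) {
  d <- dim(x$image)
  op <- par(mar = c(1, 1, 1, 1)); on.exit(par(op))
  plot(NA, xlim = c(-0.5, d[2] - 0.5), ylim = c(d[1] - 0.5, -0.5),
       asp = 1, axes = FALSE, xlab = "", ylab = "")
  rasterImage(x$image, -0.5, d[1] - 0.5, d[2] - 0.5, -0.5, interpolate = FALSE)
  if (landmarks)
    points(x$landmarks_true[, "x"], x$landmarks_true[, "y"],
           pch = 3, col = "red", cex = 0.8)
  invisible(x)
}
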