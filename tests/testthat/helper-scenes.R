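# Shared fixtures: everything is generated in code at test time.

# Compact scenes for fast tests: coarser scale in a 256 x 128 frame.
small_ranges <- function(...) {
  scene_ranges(mm_per_px = c(min = 0.44, max = 0.48),
               image_size = c(256L, 128L),
               trunc_sd = 1,
               ...)
}

# Desk-scale training configuration used by the heavier end-to-end checks:
# network input 256 x 128, 30 epochs, width-1.5 compact backbone.
desk_config <- function(seed = 1L, epochs = 30L, ...) {
  detector_config(input_size = c(256L, 128L), batch_size = 16L,
                  epochs = as.integer(epochs),
                  lr_schedule = c("1" = 1e-3, "21" = 1e-4, "28" = 1e-5),
                  seed = as.integer(seed), width = 1.5, ...)
}

# A level, noise-free, fully symmetric scene with round-number geometry.
flat_params <- function(mm_per_px = 0.25, roll = 0, noise = 0,
                        image_size = c(512L, 256L)) {
  scene_params(mrd1_right = 3.66, mrd1_left = 3.66,
               mrd2_right = 5.24, mrd2_left = 5.24,
               hpa_right = 25.3, hpa_left = 25.3,
               ipd = 61.2, iicd = 33.3, oicd = 33.3 + 2 * 25.3,
               mm_per_px_true = mm_per_px, head_roll_deg = roll,
               noise_sd = noise, image_size = image_size)
}

# Hand-built landmark set: pupils at (px_r/px_l, ey), lids/canthi offset.
toy_landmarks <- function(ey = 100, px_r = 80, px_l = 220,
                          mrd1_px = 20, mrd2_px = 25, half_iicd = 50,
                          hpa_px = 60) {
  cx <- (px_r + px_l) / 2
  lm <- rbind(
    c(px_r, ey), c(px_r, ey - mrd1_px), c(px_r, ey + mrd2_px),
    c(cx - half_iicd, ey), c(cx - half_iicd - hpa_px, ey),
    c(px_l, ey), c(px_l, ey - mrd1_px), c(px_l, ey + mrd2_px),
    c(cx + half_iicd, ey), c(cx + half_iicd + hpa_px, ey))
  landmark_set(lm)
}

expect_no_failure <- function(eval, threshold = 0) {
  expect_lte(eval$failure_rate, threshold)
}
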