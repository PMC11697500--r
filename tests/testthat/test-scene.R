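test_that("scene parameter sampling is deterministic and honours ranges", {
  p1 <- sample_scene_params(42)
  p2 <- sample_scene_params(42)
  expect_identical(p1, p2)
  p3 <- sample_scene_params(43)
  expect_false(identical(p1$mrd1_right, p3$mrd1_right))

  # collapsed ranges pin every drawn quantity to the point value
  pt <- scene_ranges(mrd1 = c(mean = 3.5, sd = 0),
                     mrd2 = c(mean = 5, sd = 0),
                     hpa = c(mean = 25, sd = 0),
                     ipd = c(mean = 61, sd = 0),
                     iicd = c(mean = 33, sd = 0),
                     mm_per_px = c(min = 0.23, max = 0.23),
                     head_roll = c(sd = 0, max = 0))
  p <- sample_scene_params(1, pt)
  expect_equal(p$mrd1_right, 3.5)
  expect_equal(p$mrd1_left, 3.5)
  expect_equal(p$mm_per_px_true, 0.23)
  expect_equal(p$head_roll_deg, 0)
  expect_equal(p$oicd, 33 + 2 * 25)
})

test_that("sampled MRD1 reproduces the configured population mean", {
  draws <- vapply(1:1000, function(s) sample_scene_params(s)$mrd1_right,
                  numeric(1))
  se <- 0.89 / sqrt(1000)
  expect_lt(abs(mean(draws) - 3.66), 3 * se)
})

test_that("infeasible ranges are rejected", {
  expect_error(sample_scene_params(1, scene_ranges(hpa = c(mean = 1, sd = 2))),
               "infeasible")
  expect_error(sample_scene_params(1, scene_ranges(
    mm_per_px = c(min = 0.3, max = 0.2))), "infeasible")
  expect_error(scene_params(mrd1_right = 3.66, mrd1_left = 3.66,
                            mrd2_right = 5.24, mrd2_left = 5.24,
                            hpa_right = 25.3, hpa_left = 25.3,
                            ipd = 61.2, iicd = 90, oicd = 84,
                            mm_per_px_true = 0.22), "oicd")
})

test_that("rendered geometry matches the analytic definitions", {
  # MRD1 of 3.66 mm at 0.1 mm/px puts the upper-lid midpoint 36.6 px above
  # the pupil centre before roll
  p <- flat_params(mm_per_px = 0.1, image_size = c(1024L, 512L))
  set.seed(1)
  s <- render_scene(p)
  lm <- s$landmarks_true
  expect_equal(unname(lm["pupil_centre_r", "y"] - lm["upper_lid_mid_r", "y"]),
               36.6, tolerance = 1e-10)

  # a 24 mm dot at 0.24 mm/px renders with radius 50 px
  p2 <- flat_params(mm_per_px = 0.24)
  set.seed(1)
  s2 <- render_scene(p2)
  expect_equal(s2$sticker_circle_true$radius, 50)
})

test_that("true measurements round-trip to the scene parameters", {
  for (seed in 1:20) {
    p <- sample_scene_params(seed)
    set.seed(seed)
    s <- render_scene(p)
    m <- s$measurements_true
    tol <- 1 * p$mm_per_px_true      # one rendered-pixel equivalent
    for (f in c("mrd1_right", "mrd1_left", "mrd2_right", "mrd2_left",
                "hpa_right", "hpa_left", "ipd", "iicd", "oicd"))
      expect_lt(abs(m[[f]] - p[[f]]), tol)
    expect_lt(abs(m$pfh_right - (p$mrd1_right + p$mrd2_right)), tol)
  }
})

test_that("Euclidean metrics are invariant to head roll", {
  base <- flat_params(noise = 0)
  rolled <- flat_params(noise = 0, roll = 4.5)
  set.seed(1); s0 <- render_scene(base)
  set.seed(1); s1 <- render_scene(rolled)
  for (f in c("ipd", "iicd", "oicd", "hpa_right", "hpa_left"))
    expect_equal(s1$measurements_true[[f]], s0$measurements_true[[f]],
                 tolerance = 1e-9)
})

test_that("scenes exceeding the frame raise a layout error", {
  p <- flat_params(mm_per_px = 0.1)   # 84 mm OICD cannot fit 512 px at 0.1
  expect_error(render_scene(p), "bounds")
})

test_that("make_dataset is reproducible and validates n", {
  expect_error(make_dataset(0, 1), "positive integer")
  d1 <- make_dataset(3, seed = 1, ranges = small_ranges())
  d2 <- make_dataset(3, seed = 1, ranges = small_ranges())
  expect_identical(attr(d1, "manifest"), attr(d2, "manifest"))
  expect_identical(d1[[2]]$landmarks_true, d2[[2]]$landmarks_true)
  expect_identical(d1[[3]]$image, d2[[3]]$image)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  f1 <- file.path(dir1, "annotations", "scene_0002.json")
  f2 <- file.path(dir2, "annotations", "scene_0002.json")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("samples in a dataset are distinct", {
  d <- make_dataset(30, seed = 9, ranges = small_ranges())
  pupils <- t(vapply(d, function(s) s$landmarks_true["pupil_centre_r", ],
                     numeric(2)))
  expect_equal(nrow(unique(pupils)), 30)
})
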