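test_that("augmentation with the identity transform returns the input", {
  set.seed(2)
  d <- make_dataset(1, seed = 3, ranges = small_ranges())[[1]]
  out <- augment_sample(d$image, d$landmarks_true, rotation = 0,
                        scale = c(1, 1), flip_prob = 0)
  expect_true(attr(out, "augmented"))
  expect_equal(out$image, d$image, tolerance = 1e-12)
  expect_equal(out$landmarks, d$landmarks_true, tolerance = 1e-12)
})

test_that("horizontal flips permute eye blocks and preserve IPD", {
  set.seed(2)
  d <- make_dataset(1, seed = 3, ranges = small_ranges())[[1]]
  lm <- d$landmarks_true
  out <- augment_sample(d$image, lm, rotation = 0, scale = c(1, 1),
                        flip_prob = 1)
  flm <- out$landmarks
  w <- dim(d$image)[2]
  # the right-pupil slot now holds the mirrored left pupil
  expect_equal(unname(flm["pupil_centre_r", ]),
               unname(c(w - 1 - lm["pupil_centre_l", "x"],
                        lm["pupil_centre_l", "y"])), tolerance = 1e-9)
  ipd_px <- function(m) sqrt(sum((m[1, ] - m[6, ])^2))
  expect_equal(ipd_px(flm), ipd_px(lm), tolerance = 1e-9)
  # roles keep anatomical meaning: medial canthi stay innermost
  expect_lt(abs(flm["medial_canthus_r", "x"] - (w - 1) / 2),
            abs(flm["lateral_canthus_r", "x"] - (w - 1) / 2))
})

test_that("rotation-scale draws act as similarities on the landmarks", {
  set.seed(5)
  d <- make_dataset(1, seed = 4, ranges = small_ranges())[[1]]
  lm <- d$landmarks_true
  pd <- as.matrix(dist(lm))
  for (i in 1:5) {
    out <- augment_sample(d$image, lm, rotation = 17, scale = c(1, 1),
                          flip_prob = 0)
    if (!attr(out, "augmented")) next
    expect_lt(max(abs(as.matrix(dist(out$landmarks)) - pd)), 1e-6)
  }
})

test_that("augmentation falls back to the original when landmarks leave the frame", {
  set.seed(1)
  d <- make_dataset(1, seed = 3, ranges = small_ranges())[[1]]
  out <- augment_sample(d$image, d$landmarks_true, rotation = 0,
                        scale = c(4, 4), flip_prob = 0)
  expect_false(attr(out, "augmented"))
  expect_identical(out$image, d$image)
})

test_that("the detector can overfit a single scene", {
  ds <- make_dataset(1, seed = 5)
  cfg <- detector_config(input_size = c(256, 128), epochs = 200,
                         batch_size = 1, aug_rotation = 0,
                         aug_scale = c(1, 1), aug_flip_prob = 0,
                         lr_schedule = c("1" = 1e-3, "150" = 2e-4),
                         seed = 3, width = 2)
  model <- train_detector(ds, cfg, eval_data = ds)
  expect_lt(tail(model$log$loss, 1), 0.01 * model$log$loss[1])
  # prediction on the training image is tight
  expect_lt(model$eval$mean_nme, 0.02)

  # inference determinism
  p1 <- predict(model, ds[[1]]$image)
  p2 <- predict(model, ds[[1]]$image)
  expect_identical(p1, p2)

  # doubling the resolution and halving the coordinates stays consistent
  img <- ds[[1]]$image
  h <- dim(img)[1]; w <- dim(img)[2]
  up <- periometry:::warp_image(img, periometry:::affine_resize(w, h, 2 * w, 2 * h),
                                2 * w, 2 * h)
  expect_lt(max(abs(predict(model, up) / 2 - p1)), 2)
})

test_that("the train/evaluation split is a deterministic partition", {
  ds <- make_dataset(8, seed = 6, ranges = small_ranges())
  cfg <- detector_config(input_size = c(128, 64), epochs = 1, batch_size = 4,
                         seed = 11, width = 0.5)
  m1 <- train_detector(ds, cfg)
  m2 <- train_detector(ds, cfg)
  expect_identical(m1$split, m2$split)
  expect_length(intersect(m1$split$train, m1$split$eval), 0)
  expect_setequal(c(m1$split$train, m1$split$eval), 1:8)
  expect_error(train_detector(ds[1], cfg), "configuration error")
})

test_that("NME evaluation matches its definition and closed forms", {
  lm <- toy_landmarks()
  expect_equal(evaluate_landmarks(list(lm), list(lm))$mean_nme, 0)
  expect_equal(evaluate_landmarks(list(lm), list(lm))$failure_rate, 0)

  # uniform offset d on every landmark gives NME = d / IPD exactly
  d <- 7
  off <- lm; off[, "x"] <- off[, "x"] + d
  D <- sqrt(sum((lm[1, ] - lm[6, ])^2))
  ev <- evaluate_landmarks(list(off), list(lm))
  expect_equal(ev$mean_nme, d / D, tolerance = 1e-12)

  # random perturbations against a naive per-landmark loop
  set.seed(8)
  preds <- truths <- list()
  for (i in 1:5) {
    t <- toy_landmarks(ey = runif(1, 80, 120))
    p <- t + matrix(rnorm(20, 0, 3), 10, 2)
    truths[[i]] <- t; preds[[i]] <- p
  }
  ev <- evaluate_landmarks(preds, truths)
  naive <- numeric(5)
  for (i in 1:5) {
    s <- 0
    for (l in 1:10)
      s <- s + sqrt(sum((preds[[i]][l, ] - truths[[i]][l, ])^2))
    naive[i] <- (s / 10) / sqrt(sum((truths[[i]][1, ] - truths[[i]][6, ])^2))
  }
  expect_lt(max(abs(ev$per_image_nme - naive)), 1e-12)

  # scale invariance
  ev2 <- evaluate_landmarks(lapply(preds, `*`, 3), lapply(truths, `*`, 3))
  expect_equal(ev2$per_image_nme, ev$per_image_nme, tolerance = 1e-12)

  # degenerate ground truth
  z <- lm; z[6, ] <- z[1, ]
  expect_error(evaluate_landmarks(list(lm), list(z)), "inter-pupillary")
  expect_error(evaluate_landmarks(list(lm), list(lm, lm)), "equal length")
})
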