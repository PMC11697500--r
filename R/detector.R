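#' Training configuration for the landmark detector
#'
#' Defaults follow the reference photographic training protocol: 512 x 256
#' input, Adam with mini-batches of 16 for 60 epochs, base learning rate
#' 1e-3 decaying to 1e-4 at epoch 30 and 1e-5 at epoch 50, augmentation by
#' in-plane rotation (+/- 30 degrees), isotropic scaling (0.75-1.25) and
#' horizontal flips (probability 0.5), and a 70/30 train/evaluation split.
#'
#' @param input_size `c(width, height)` the network operates at; images are
#'   stretched (anisotropically) to this size and predictions mapped back.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (>= 1).
#' @param lr_schedule Named numeric vector: learning rate taking effect at
#'   the epoch given by each name; values must be positive, non-increasing.
#' @param aug_rotation,aug_scale,aug_flip_prob Augmentation parameters; see
#'   [augment_sample()].
#' @param split_fraction Fraction of samples used for training (0-1).
#' @param seed Seed controlling split, weight init and augmentation.
#' @param backbone Backbone identifier; `"compact"` is built in, others may
#'   be registered via [register_backbone()].
#' @param width Channel-width multiplier of the compact backbone.
#' @param sigma Gaussian SD of the target heatmaps, heatmap px.
#' @param stride Heatmap stride (output resolution = input / stride).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(input_size = c(512L, 256L), batch_size = 16L,
                            epochs = 60L,
                            lr_schedule = c("1" = 1e-3, "30" = 1e-4, "50" = 1e-5),
                            aug_rotation = 30, aug_scale = c(0.75, 1.25),
                            aug_flip_prob = 0.5, split_fraction = 0.70,
                            seed = 1L, backbone = "compact", width = 1,
                            sigma = 2, stride = 4L) {
  if (!(split_fraction > 0 && split_fraction < 1))
    stop("split_fraction must lie strictly between 0 and 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (any(lr_schedule <= 0) || is.unsorted(rev(lr_schedule)))
    stop("learning rates must be positive and non-increasing across milestones")
  if (any(input_size %% stride != 0))
    stop("input_size must be a multiple of the stride")
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 aug_rotation = aug_rotation, aug_scale = aug_scale,
                 aug_flip_prob = aug_flip_prob,
                 split_fraction = split_fraction, seed = as.integer(seed),
                 backbone = backbone, width = width, sigma = sigma,
                 stride = as.integer(stride)),
            class = "detector_config")
}

lr_at <- function(schedule, epoch) {
  starts <- as.integer(names(schedule))
  schedule[[max(which(starts <= epoch))]]
}

# backbone registry: list(init(width), forward(par, x, keep), backward(...))
the_backbones <- new.env(parent = emptyenv())

#' Register a detector backbone
#'
#' A backbone is a list of three functions: `init(width)` returning the
#' parameter list, `forward(par, x, keep)` mapping an H x W x 3 input array
#' to an (H/4) x (W/4) x 10 heatmap array (returning a cache list when
#' `keep = TRUE`), and `backward(par, cache, dout)` returning gradients with
#' the same names as the parameters.
#'
#' @param name Identifier used in [detector_config()].
#' @param backbone List with elements `init`, `forward`, `backward`.
#' @export
register_backbone <- function(name, backbone) {
  stopifnot(all(c("init", "forward", "backward") %in% names(backbone)))
  assign(name, backbone, envir = the_backbones)
  invisible(name)
}

get_backbone <- function(name) {
  if (name == "compact")
    return(list(init = compact_init, forward = compact_forward,
                backward = compact_backward))
  if (!exists(name, envir = the_backbones))
    stop("unknown backbone '", name, "'")
  get(name, envir = the_backbones)
}

as_training_pairs <- function(dataset) {
  lapply(dataset, function(s) {
    if (inherits(s, "synthetic_sample"))
      list(image = s$image, landmarks = s$landmarks_true)
    else if (!is.null(s$image) && !is.null(s$landmarks))
      list(image = s$image, landmarks = landmark_set(s$landmarks))
    else stop("dataset elements must be synthetic samples or ",
              "image/landmarks pairs")
  })
}

# resize a pair into the network frame, returning the luminance raster,
# input-frame landmarks and the forward affine
to_input_frame <- function(image, landmarks, input_size) {
  h <- dim(image)[1]; w <- dim(image)[2]
  M <- affine_resize(w, h, input_size[1], input_size[2])
  gry <- net_input(image)[, , 1]
  x <- warp_image(array(gry, dim = c(h, w, 1)), M,
                  input_size[1], input_size[2])
  list(x = x, landmarks = affine_apply(M, landmarks), transform = M)
}

with_coords <- function(gray1) {
  h <- dim(gray1)[1]; w <- dim(gray1)[2]
  xn <- matrix((0:(w - 1)) / (w - 1) * 2 - 1, h, w, byrow = TRUE)
  yn <- matrix((0:(h - 1)) / (h - 1) * 2 - 1, h, w)
  array(c(gray1[, , 1], xn, yn), dim = c(h, w, 3))
}

#' Train the heatmap-regression landmark detector
#'
#' Fits a compact (or registered) backbone to images with ten annotated
#' periocular landmarks by minimising the mean-squared error between
#' predicted and Gaussian-encoded ground-truth heatmaps, with affine/flip
#' augmentation and an Adam learning-rate schedule. The train/evaluation
#' split is drawn deterministically from `config$seed` at the face level
#' (one image per face); alternatively pass an explicit `eval_data` to use
#' `dataset` in full for training.
#'
#' @param dataset A [make_dataset()] result, or a list of
#'   `list(image, landmarks)` pairs.
#' @param config A [detector_config()].
#' @param eval_data Optional held-out data of the same form; when supplied,
#'   no internal split is made.
#' @param verbose Print per-epoch loss.
#' @return An object of class `landmark_detector`: parameters, config,
#'   per-epoch training log, split indices, and the held-out evaluation
#'   ([evaluate_landmarks()]) when evaluation data exist.
#' @export
train_detector <- function(dataset, config = detector_config(),
                           eval_data = NULL, verbose = FALSE) {
  pairs <- as_training_pairs(dataset)
  if (!length(pairs)) stop("dataset is empty")
  set.seed(config$seed)
  if (is.null(eval_data)) {
    n <- length(pairs)
    idx <- sample.int(n)
    ntr <- round(config$split_fraction * n)
    if (ntr < 1 || ntr >= n)
      stop("configuration error: train/evaluation split has an empty partition")
    train_idx <- sort(idx[seq_len(ntr)])
    eval_idx <- sort(idx[(ntr + 1):n])
    train_pairs <- pairs[train_idx]
    eval_pairs <- pairs[eval_idx]
  } else {
    train_idx <- seq_along(pairs)
    eval_idx <- integer(0)
    train_pairs <- pairs
    eval_pairs <- as_training_pairs(eval_data)
  }

  inp <- lapply(train_pairs, function(p)
    to_input_frame(p$image, p$landmarks, config$input_size))

  bb <- get_backbone(config$backbone)
  par <- bb$init(config$width)
  state <- adam_state(par)
  ntr <- length(inp)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))
  aug_skipped <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(config$lr_schedule, epoch)
    order_idx <- sample.int(ntr)
    epoch_loss <- 0
    b0 <- 1
    while (b0 <= ntr) {
      batch <- order_idx[b0:min(b0 + config$batch_size - 1, ntr)]
      grads <- NULL
      for (i in batch) {
        aug <- augment_sample(inp[[i]]$x, inp[[i]]$landmarks,
                              rotation = config$aug_rotation,
                              scale = config$aug_scale,
                              flip_prob = config$aug_flip_prob)
        if (!attr(aug, "augmented")) aug_skipped <- aug_skipped + 1L
        x <- with_coords(aug$image)
        target <- encode_heatmaps(aug$landmarks, config$input_size,
                                  config$stride, config$sigma)
        cache <- bb$forward(par, x, keep = TRUE)
        diff <- cache$out - target
        epoch_loss <- epoch_loss + mean(diff^2)
        g <- bb$backward(par, cache, 2 * diff / length(diff))
        grads <- if (is.null(grads)) g
                 else Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, length(batch))
      upd <- adam_step(par, grads, state, lr)
      par <- upd$par; state <- upd$state
      b0 <- b0 + config$batch_size
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = epoch_loss / ntr))
    if (verbose)
      message(sprintf("epoch %3d  lr %.0e  loss %.6f", epoch, lr,
                      epoch_loss / ntr))
  }

  model <- structure(list(par = par, config = config, log = log,
                          split = list(train = train_idx, eval = eval_idx),
                          aug_skipped = aug_skipped),
                     class = "landmark_detector")
  if (length(eval_pairs)) {
    preds <- lapply(eval_pairs, function(p) predict(model, p$image))
    truths <- lapply(eval_pairs, function(p) p$landmarks)
    model$eval <- evaluate_landmarks(preds, truths)
  }
  model
}

#' Predict landmarks on an image
#'
#' Stretches the image to the network input size, runs the backbone, decodes
#' the predicted heatmaps ([decode_heatmaps()]), and maps the coordinates
#' back to the original image resolution through the inverse of the resize
#' transform.
#'
#' @param object A trained `landmark_detector`.
#' @param image H x W x 3 (or H x W) array in `[0, 1]`, or a list of such.
#' @param ... Unused.
#' @return A 10 x 2 landmark coordinate matrix (or list thereof).
#' @export
predict.landmark_detector <- function(object, image, ...) {
  if (is.list(image) && is.null(dim(image)))
    return(lapply(image, function(im) predict.landmark_detector(object, im)))
  h <- dim(image)[1]; w <- dim(image)[2]
  cfg <- object$config
  M <- affine_resize(w, h, cfg$input_size[1], cfg$input_size[2])
  gry <- net_input(image)[, , 1]
  x <- warp_image(array(gry, dim = c(h, w, 1)), M,
                  cfg$input_size[1], cfg$input_size[2])
  out <- get_backbone(cfg$backbone)$forward(object$par, with_coords(x))
  lm_in <- decode_heatmaps(out, cfg$stride)
  affine_apply(affine_invert(M), lm_in)
}

#' @export
print.landmark_detector <- function(x, ...) {
  cat(sprintf("Landmark detector ('%s' backbone, input %d x %d, stride %d)\n",
              x$config$backbone, x$config$input_size[1],
              x$config$input_size[2], x$config$stride))
  cat(sprintf("  trained %d epochs on %d images; final heatmap loss %.3g\n",
              nrow(x$log), length(x$split$train), tail(x$log$loss, 1)))
  if (!is.null(x$eval))
    cat(sprintf("  held-out (n = %d): mean NME %.4f, failure rate @%.2f = %.1f%%\n",
                length(x$eval$per_image_nme), x$eval$mean_nme,
                x$eval$threshold, 100 * x$eval$failure_rate))
  invisible(x)
}

#' @export
plot.landmark_detector <- function(x, ...) {
  plot(x$log$epoch, x$log$loss, type = "b", log = "y", xlab = "epoch",
       ylab = "mean heatmap MSE", main = "Detector training loss", ...)
  invisible(x)
}

#' Evaluate landmark predictions
#'
#' Per image, the normalised mean error (NME) is the mean over the ten
#' landmarks of the Euclidean localisation error divided by the ground-truth
#' inter-pupillary pixel distance. The failure rate is the fraction of
#' images whose NME exceeds `threshold`.
#'
#' @param predictions,truths Index-aligned lists of 10 x 2 coordinate
#'   matrices.
#' @param threshold NME failure threshold (default 0.1).
#' @return A list of class `landmark_eval`: `per_image_nme`, `mean_nme`,
#'   `failure_rate`, `threshold`.
#' @export
evaluate_landmarks <- function(predictions, truths, threshold = 0.1) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must be index-aligned lists of equal length")
  nme <- mapply(function(p, t) {
    p <- as.matrix(p); t <- as.matrix(t)
    ipd <- sqrt(sum((t[1, ] - t[6, ])^2))
    if (ipd == 0) stop("zero inter-pupillary distance in ground truth")
    mean(sqrt(rowSums((p - t)^2))) / ipd
  }, predictions, truths)
  structure(list(per_image_nme = as.numeric(nme), mean_nme = mean(nme),
                 failure_rate = mean(nme > threshold), threshold = threshold),
            class = "landmark_eval")
}

#' @export
print.landmark_eval <- function(x, ...) {
  cat(sprintf("Landmark evaluation on %d images: mean NME %.4f (%.2f%%), failure rate @%.2f = %.1f%%\n",
              length(x$per_image_nme), x$mean_nme, 100 * x$mean_nme,
              x$threshold, 100 * x$failure_rate))
  invisible(x)
}

#' @importFrom utils tail
NULL
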