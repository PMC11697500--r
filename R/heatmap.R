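#' Encode landmarks as Gaussian heatmaps
#'
#' Produces one likelihood map per landmark at `1/stride` of the image
#' resolution. Each map is a 2D Gaussian centred on the landmark's quantized
#' heatmap cell with peak value 1, truncated to 0 beyond `3 * sigma` heatmap
#' pixels.
#'
#' @param landmarks A [landmark_set()] in image coordinates.
#' @param image_size `c(width, height)` in px; both must be multiples of
#'   `stride`.
#' @param stride Downsampling factor (default 4).
#' @param sigma Gaussian SD in heatmap pixels (default 2).
#' @return Array of dim `c(height/stride, width/stride, 10)` of class
#'   `heatmap_stack`, with attributes `stride` and `sigma`.
#' @export
encode_heatmaps <- function(landmarks, image_size, stride = 4L, sigma = 2) {
  lm <- landmark_set(landmarks)
  w <- image_size[1]; h <- image_size[2]
  if (w %% stride != 0 || h %% stride != 0)
    stop("image size must be a multiple of the stride")
  bad <- which(lm[, "x"] < 0 | lm[, "x"] > w - 1 |
               lm[, "y"] < 0 | lm[, "y"] > h - 1)
  if (length(bad))
    stop("cannot encode landmark(s) outside the image: index ",
         paste(bad, collapse = ", "))
  hw <- w %/% stride; hh <- h %/% stride
  maps <- array(0, dim = c(hh, hw, 10L))
  rad <- ceiling(3 * sigma)
  for (l in 1:10) {
    cx <- floor(lm[l, "x"] / stride + 0.5)     # quantized heatmap cell
    cy <- floor(lm[l, "y"] / stride + 0.5)
    cx <- min(max(cx, 0), hw - 1)
    cy <- min(max(cy, 0), hh - 1)
    us <- max(0, cx - rad):min(hw - 1, cx + rad)
    vs <- max(0, cy - rad):min(hh - 1, cy + rad)
    d2 <- outer((vs - cy)^2, (us - cx)^2, "+")
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > (3 * sigma)^2] <- 0
    maps[vs + 1, us + 1, l] <- g
  }
  structure(maps, stride = as.integer(stride), sigma = sigma,
            class = "heatmap_stack")
}

#' Mean-squared-error heatmap loss
#'
#' Mean of squared elementwise differences over all maps; the reduction is a
#' mean (not a sum) so the value is independent of map size and batch
#' composition.
#'
#' @param predicted,truth Heatmap stacks (or plain arrays) of equal shape.
#' @return Non-negative scalar.
#' @export
mse_heatmap_loss <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("heatmap stacks have mismatched shapes")
  mean((predicted - truth)^2)
}

#' Decode heatmaps to sub-pixel landmark coordinates
#'
#' For each map, takes the argmax cell (ties broken by row-major first
#' occurrence: scanning rows top-to-bottom, left-to-right within a row),
#' shifts a quarter heatmap pixel toward the larger of each axis pair of
#' 4-neighbours (no shift on ties or when both neighbours are absent), and
#' multiplies by the stride to return image coordinates.
#'
#' @param predicted Array `(hh, hw, L)` of predicted maps.
#' @param stride Upsampling factor back to image resolution (default 4).
#' @return A [landmark_set()] when `L = 10`, else a plain L x 2 matrix.
#' @export
decode_heatmaps <- function(predicted, stride = 4L) {
  d <- dim(predicted)
  if (length(d) != 3) stop("expected a 3-d heatmap array")
  hh <- d[1]; hw <- d[2]; L <- d[3]
  out <- matrix(NA_real_, L, 2)
  for (l in seq_len(L)) {
    m <- predicted[, , l]
    if (all(is.na(m))) stop("all-NaN heatmap for landmark index ", l)
    m[is.na(m)] <- -Inf
    # row-major first occurrence: scan transposed (column-major) matrix
    idx <- which.max(t(m)) - 1L
    v <- idx %/% hw          # 0-based row (y)
    u <- idx %% hw           # 0-based col (x)
    val <- function(vv, uu) if (uu < 0 || uu >= hw || vv < 0 || vv >= hh) 0
                            else m[vv + 1, uu + 1]
    du <- 0.25 * sign(val(v, u + 1) - val(v, u - 1))
    dv <- 0.25 * sign(val(v + 1, u) - val(v - 1, u))
    out[l, ] <- c((u + du) * stride, (v + dv) * stride)
  }
  colnames(out) <- c("x", "y")
  if (L == 10L) rownames(out) <- landmark_names()
  out
}
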