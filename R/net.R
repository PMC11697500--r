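# Compact encoder-decoder backbone for heatmap regression.
#
# Input: 3 channels (luminance + normalised x and y coordinate maps); the
# coordinate channels give the otherwise locally-ambiguous landmark roles
# (right vs left eye, medial vs lateral canthus) a positional cue, which is
# what lets a small receptive-field network separate the ten roles.
#
# conv3 s2 3->c1 | conv3 s2 c1->c2 | conv3 s2 c2->c3 | conv3 s1 c3->c3
# | up2 | conv3 s1 c3->c2 (+skip from stage 2) | conv1 s1 c2->10
#
# Three stride-2 stages reach 1/8 resolution; one upsampling returns to 1/4,
# where the skip from stage 2 re-injects higher-resolution features, so the
# output stride is 4.

compact_channels <- function(width = 1) {
  ch <- round(c(8, 16, 24) * width)
  list(c1 = ch[1], c2 = ch[2], c3 = ch[3])
}

he_init <- function(oc, ic, k) {
  matrix(rnorm(oc * ic * k * k, 0, sqrt(2 / (ic * k * k))), oc, ic * k * k)
}

compact_init <- function(width = 1, n_out = 10L) {
  ch <- compact_channels(width)
  list(
    W1 = he_init(ch$c1, 3, 3),      b1 = numeric(ch$c1),
    W2 = he_init(ch$c2, ch$c1, 3),  b2 = numeric(ch$c2),
    W3 = he_init(ch$c3, ch$c2, 3),  b3 = numeric(ch$c3),
    W4 = he_init(ch$c3, ch$c3, 3),  b4 = numeric(ch$c3),
    W5 = he_init(ch$c2, ch$c3, 3),  b5 = numeric(ch$c2),
    W6 = he_init(n_out, ch$c2, 1) * 0.1, b6 = numeric(n_out)
  )
}

relu <- function(x) { x[x < 0] <- 0; x }

compact_forward <- function(par, x, keep = FALSE) {
  a1 <- .conv_fw(x, par$W1, par$b1, 3L, 2L); r1 <- relu(a1)
  a2 <- .conv_fw(r1, par$W2, par$b2, 3L, 2L); r2 <- relu(a2)
  a3 <- .conv_fw(r2, par$W3, par$b3, 3L, 2L); r3 <- relu(a3)
  a4 <- .conv_fw(r3, par$W4, par$b4, 3L, 1L); r4 <- relu(a4)
  u <- .upsample2_fw(r4)
  a5 <- .conv_fw(u, par$W5, par$b5, 3L, 1L)
  s5 <- a5 + r2                                  # skip connection
  r5 <- relu(s5)
  out <- .conv_fw(r5, par$W6, par$b6, 1L, 1L)
  if (!keep) return(out)
  list(out = out, x = x, a1 = a1, r1 = r1, a2 = a2, r2 = r2, a3 = a3,
       r3 = r3, a4 = a4, r4 = r4, u = u, s5 = s5, r5 = r5)
}

compact_backward <- function(par, cache, dout) {
  g <- list()
  b6 <- .conv_bw(cache$r5, par$W6, dout, 1L, 1L)
  g$W6 <- b6$dw; g$b6 <- b6$db
  d5 <- b6$dx * (cache$s5 > 0)
  b5 <- .conv_bw(cache$u, par$W5, d5, 3L, 1L)
  g$W5 <- b5$dw; g$b5 <- b5$db
  d4 <- .upsample2_bw(b5$dx) * (cache$a4 > 0)
  b4 <- .conv_bw(cache$r3, par$W4, d4, 3L, 1L)
  g$W4 <- b4$dw; g$b4 <- b4$db
  d3 <- b4$dx * (cache$a3 > 0)
  b3 <- .conv_bw(cache$r2, par$W3, d3, 3L, 2L)
  g$W3 <- b3$dw; g$b3 <- b3$db
  d2 <- (b3$dx + d5) * (cache$a2 > 0)            # skip carries grad to r2
  b2 <- .conv_bw(cache$r1, par$W2, d2, 3L, 2L)
  g$W2 <- b2$dw; g$b2 <- b2$db
  d1 <- b2$dx * (cache$a1 > 0)
  b1 <- .conv_bw(cache$x, par$W1, d1, 3L, 2L)
  g$W1 <- b1$dw; g$b1 <- b1$db
  g
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# luminance + coordinate channels, H x W x 3
net_input <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  gry <- if (length(dim(image)) == 3)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image
  xn <- matrix((0:(w - 1)) / (w - 1) * 2 - 1, h, w, byrow = TRUE)
  yn <- matrix((0:(h - 1)) / (h - 1) * 2 - 1, h, w)
  array(c(gry, xn, yn), dim = c(h, w, 3))
}
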