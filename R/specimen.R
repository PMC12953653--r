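# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a phantom ground-truth specimen
#'
#' Procedural stand-ins for captured microscope ground truth. Four styles:
#' \describe{
#'   \item{texture}{band-limited colored noise with correlated RGB channels,
#'     resembling stained tissue texture}
#'   \item{cells}{dart-thrown (minimum-distance) elliptical cells with dark
#'     membranes and tinted cytoplasm on a bright-field background}
#'   \item{grating}{a sinusoidal intensity grating of known frequency}
#'   \item{usaf}{dark bar triplets on a bright background at exponentially
#'     spaced scales, adjacent elements' bar periods in the standard
#'     resolution-chart ratio 2^(1/6)}
#' }
#' Pixel values stay inside roughly [0.06, 0.94] so that additive sensor
#' noise rarely clips. Deterministic for a fixed (seed, style, size).
#'
#' @param seed integer RNG seed
#' @param size image side in pixels (even; default 512)
#' @param style one of `"texture"`, `"cells"`, `"grating"`, `"usaf"`
#' @param grating_freq cycles per image for the grating style
#' @param grating_angle grating orientation in radians (0 = vertical bars)
#' @return object of class `specimen`: list with `pixels` (size x size x 3
#'   in [0,1]), `style`, `seed` and style-specific `meta`
#' @export
generate_specimen <- function(seed, size = 512L,
                              style = c("texture", "cells", "grating", "usaf"),
                              grating_freq = 16, grating_angle = 0) {
  style <- match.arg(style)
  if (size %% 2L != 0L) stop("size must be even")
  px <- with_seed(seed, switch(style,
    texture = specimen_texture(size),
    cells = specimen_cells(size),
    grating = specimen_grating(size, grating_freq, grating_angle),
    usaf = specimen_usaf(size)))
  structure(list(pixels = clip01(px$pixels), style = style, seed = seed,
                 size = as.integer(size), meta = px$meta),
            class = "specimen")
}

specimen_texture <- function(size) {
  # band-limited noise: white noise low-passed with a Gaussian spectral
  # envelope at two scales, mixed into correlated RGB
  ix <- c(0:(size / 2 - 1), -(size / 2):-1)
  fr2 <- outer(ix^2, ix^2, "+")
  envelope <- function(s) exp(-fr2 / (2 * s^2))
  field <- function(s) {
    w <- matrix(stats::rnorm(size^2), size)
    f <- Re(ifft2(fft2(w) * envelope(s)))
    (f - mean(f)) / stats::sd(f)
  }
  base <- field(size / 40)
  fine <- field(size / 10)
  lum <- 0.5 + 0.16 * base + 0.08 * fine
  chroma1 <- 0.08 * field(size / 24)
  chroma2 <- 0.05 * field(size / 24)
  out <- array(0, c(size, size, 3))
  out[, , 1] <- lum + chroma1
  out[, , 2] <- lum - 0.5 * chroma1 + chroma2
  out[, , 3] <- lum - chroma1 - chroma2
  # smooth range compression into (0.06, 0.94): no pixel mass piles up at
  # the bounds, so additive sensor noise almost never clips
  list(pixels = 0.5 + 0.44 * tanh((out - 0.5) / 0.55), meta = list())
}

specimen_cells <- function(size) {
  n_target <- max(6L, round((size / 64)^2 * 4))
  min_dist <- size / sqrt(n_target) * 0.7
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_target && tries < n_target * 60L) {
    tries <- tries + 1L
    cand <- stats::runif(2, size * 0.06, size * 0.94)
    if (!nrow(centers) ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_dist)
      centers <- rbind(centers, cand)
  }
  bg <- 0.88
  out <- array(bg, c(size, size, 3))
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  for (i in seq_len(nrow(centers))) {
    a <- stats::runif(1, size / 22, size / 9)       # semi-axes
    b <- a * stats::runif(1, 0.55, 1)
    th <- stats::runif(1, 0, pi)
    tint <- c(stats::runif(1, 0.55, 0.8), stats::runif(1, 0.45, 0.7),
              stats::runif(1, 0.6, 0.85))
    mem <- tint * 0.45                               # dark membrane
    dx <- xs - centers[i, 1]; dy <- ys - centers[i, 2]
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    rr <- sqrt(u^2 + v^2)
    inner <- rr < 0.82
    ring <- rr >= 0.82 & rr <= 1
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[inner] <- tint[ch]
      pl[ring] <- mem[ch]
      out[, , ch] <- pl
    }
    # nucleus
    nuc <- rr < stats::runif(1, 0.2, 0.35)
    for (ch in 1:3) {
      pl <- out[, , ch]; pl[nuc] <- mem[ch] * 0.9; out[, , ch] <- pl
    }
  }
  list(pixels = pmin(pmax(out, 0.06), 0.94),
       meta = list(n_cells = nrow(centers)))
}

specimen_grating <- function(size, freq, angle) {
  xs <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 1, size, size)
  phase <- 2 * pi * freq * (xs * cos(angle) + ys * sin(angle)) / size
  g <- 0.5 + 0.4 * sin(phase)
  list(pixels = array(g, c(size, size, 3)),
       meta = list(freq = freq, angle = angle))
}

specimen_usaf <- function(size) {
  bg <- 0.92; fg <- 0.08
  img <- matrix(bg, size, size)
  # elements at exponentially spaced scales: adjacent bar periods differ by
  # 2^(1/6), as on a MIL-STD-150A resolution chart
  base_period <- size / 8
  periods <- base_period / 2^((0:11) / 6)
  y <- round(size * 0.06)
  x <- round(size * 0.06)
  col_h <- 0L
  for (p in periods) {
    bw <- max(1L, round(p / 2))         # bar width = half period
    len <- 5L * bw
    need <- max(len, 5L * bw) + bw
    if (y + need > size * 0.94) {
      y <- round(size * 0.06)
      x <- x + col_h + round(size * 0.04)
      col_h <- 0L
    }
    if (x + 2L * len + 4L * bw > size * 0.94) break
    # three vertical bars
    for (k in 0:2) {
      c0 <- x + k * 2L * bw
      img[y:(y + len - 1L), c0:(c0 + bw - 1L)] <- fg
    }
    # three horizontal bars to the right
    hx <- x + 6L * bw + bw
    for (k in 0:2) {
      r0 <- y + k * 2L * bw
      img[r0:(r0 + bw - 1L), hx:(hx + len - 1L)] <- fg
    }
    col_h <- max(col_h, hx + len - x)
    y <- y + len + 2L * bw
  }
  list(pixels = array(img, c(size, size, 3)),
       meta = list(periods = periods, periods_px = 2 * pmax(1, round(periods / 2)),
                   period_ratio = 2^(1 / 6)))
}
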