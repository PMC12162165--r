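#' Estimate the translation between two speckle frames
#'
#' Computes the zero-mean normalized cross-correlation between the two
#' frames in the Fourier domain (cyclic), locates the correlation peak and
#' refines it per axis with 3-point parabolic interpolation. Mean removal
#' makes the estimate insensitive to global illumination drift.
#'
#' The returned `(dx, dy)` is the translation that maps `ref` onto `frame`
#' (x = column index increasing rightward, y = row index increasing
#' downward): if `frame` shows the same pattern moved 3 px to the right,
#' `dx = 3`.
#'
#' @param ref,frame Numeric matrices of identical dimensions.
#' @param subpixel If `TRUE` (default) apply parabolic peak refinement.
#' @return Named numeric vector `c(dx, dy)` in pixels.
#' @examples
#' scr <- make_phase_screen(128, seed = 7, frame_size = 56)
#' a <- render_frame(scr, c(0, 0), frame_size = 56, read_noise_dn = 0)
#' b <- render_frame(scr, c(3, -2), frame_size = 56, read_noise_dn = 0)
#' estimate_shift(a, b)
#' @export
estimate_shift <- function(ref, frame, subpixel = TRUE) {
  if (!all(dim(ref) == dim(frame))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate input: constant frame has no correlation peak",
         call. = FALSE)
  }
  # c(tau) = sum_x a(x) b(x + tau): peak at tau = shift of b relative to a
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  n_r <- nrow(cc); n_c <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(vals, at, n) {
    im <- function(i) vals[((i - 1) %% n) + 1]
    c0 <- im(at); cm <- im(at - 1); cp <- im(at + 1)
    denom <- cm - 2 * c0 + cp
    delta <- if (denom < 0) 0.5 * (cm - cp) / denom else 0
    if (!is.finite(delta) || abs(delta) > 0.5) delta <- 0
    # map index to signed cyclic displacement
    d <- (at - 1)
    if (d > n / 2) d <- d - n
    d + delta
  }
  dy <- if (subpixel) refine(cc[, pk[2]], pk[1], n_r) else {
    d <- pk[1] - 1; if (d > n_r / 2) d - n_r else d
  }
  dx <- if (subpixel) refine(cc[pk[1], ], pk[2], n_c) else {
    d <- pk[2] - 1; if (d > n_c / 2) d - n_c else d
  }
  c(dx = dx, dy = dy)
}

#' Track speckle displacement through a video
#'
#' Converts a speckle video into per-frame displacement traces by
#' cross-correlating frames ([estimate_shift()]). In `"sequential"` mode
#' (default, robust to slow pattern decorrelation) consecutive-frame shifts
#' are accumulated by summation; in `"anchored"` mode every frame is
#' correlated against frame 1. The first differences (`dpos`) are the
#' per-frame velocity channels.
#'
#' @param video A `speckle_video` object, or an H x W x T numeric array
#'   (metadata then taken from `fps` and `video_tag`).
#' @param mode `"sequential"` or `"anchored"`.
#' @param fps,video_tag Metadata overrides when `video` is a bare array.
#' @return Object of class `"displacement_trace"`: list with `pos_x`,
#'   `pos_y` (px, length T, relative to frame 1), `dpos_x`, `dpos_y`
#'   (px/frame, length T - 1), `fps`, `video_tag`, `mode`.
#' @export
track <- function(video, mode = c("sequential", "anchored"),
                  fps = NULL, video_tag = NULL) {
  mode <- match.arg(mode)
  if (inherits(video, "speckle_video")) {
    frames <- video$frames
    fps <- video$fps
    video_tag <- video$video_tag
  } else {
    frames <- video
    if (is.null(fps)) fps <- 200
    if (is.null(video_tag)) video_tag <- "video"
  }
  n <- dim(frames)[3]
  if (is.na(n) || n < 2) stop("need at least 2 frames to track", call. = FALSE)
  sx <- sy <- numeric(n)
  if (mode == "anchored") {
    f1 <- frames[, , 1]
    for (k in 2:n) {
      s <- estimate_shift(f1, frames[, , k])
      sx[k] <- s[1]; sy[k] <- s[2]
    }
  } else {
    prev <- frames[, , 1]
    acc <- c(0, 0)
    for (k in 2:n) {
      cur <- frames[, , k]
      acc <- acc + estimate_shift(prev, cur)
      sx[k] <- acc[1]; sy[k] <- acc[2]
      prev <- cur
    }
  }
  structure(list(pos_x = sx, pos_y = sy,
                 dpos_x = diff(sx), dpos_y = diff(sy),
                 fps = fps, video_tag = video_tag, mode = mode),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("Displacement trace '%s' (%s): %d frames @ %g FPS\n",
              x$video_tag, x$mode, length(x$pos_x), x$fps))
  cat(sprintf("  pos_x RMS %.3f px | pos_y RMS %.3f px\n",
              sqrt(mean(x$pos_x^2)), sqrt(mean(x$pos_y^2))))
  invisible(x)
}

#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  data.frame(frame_idx = seq_along(x$pos_x),
             pos_x = x$pos_x, pos_y = x$pos_y,
             dpos_x = c(NA, x$dpos_x), dpos_y = c(NA, x$dpos_y))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided magnitude spectrum normalized so that sum(magnitude^2) equals
# the time-domain energy sum(x^2) of the (windowed) series.
.one_sided_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2) + 1
  w <- rep(2, half)
  w[1] <- 1
  if (n %% 2 == 0) w[half] <- 1
  list(freqs = (0:(half - 1)) * fs / n,
       magnitude = Mod(X[1:half]) * sqrt(w / n))
}

#' Vibration spectrum of a displacement channel
#'
#' One-sided magnitude spectrum of a trace channel after optional mean
#' removal and windowing. Magnitudes are energy-normalized: with a
#' rectangular window and no detrending, `sum(magnitude^2)` equals the
#' time-domain energy `sum(x^2)` (Parseval).
#'
#' @param trace A [track()] result.
#' @param channel One of `"pos_x"`, `"pos_y"`, `"dpos_x"`, `"dpos_y"`.
#' @param detrend Remove the channel mean first (default `TRUE`).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @return Object of class `"vibration_spectrum"`: list with `freqs`
#'   (Hz, 0 to fps/2, length `floor(n/2) + 1`) and `magnitude` (>= 0).
#' @export
vibration_spectrum <- function(trace, channel = "pos_x", detrend = TRUE,
                               window = c("hann", "rectangular")) {
  window <- match.arg(window)
  if (!channel %in% c("pos_x", "pos_y", "dpos_x", "dpos_y")) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  x <- trace[[channel]]
  if (length(x) < 8) stop("trace too short for a spectrum", call. = FALSE)
  if (detrend) x <- x - mean(x)
  if (window == "hann") x <- x * .hann(length(x))
  sp <- .one_sided_spectrum(x, trace$fps)
  structure(list(freqs = sp$freqs, magnitude = sp$magnitude,
                 channel = channel, window = window),
            class = "vibration_spectrum")
}

#' @export
plot.vibration_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$magnitude, type = "h",
                 xlab = "frequency (Hz)", ylab = "magnitude",
                 main = paste("Vibration spectrum:", x$channel), ...)
  invisible(x)
}
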