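#' Random surface-roughness phase screen
#'
#' Generates the random phase map imposed on coherent light by a rough
#' reflecting surface. Phases are i.i.d. uniform on `[0, 2*pi)`, which in
#' the far field yields fully developed speckle (negative-exponential
#' intensity statistics, contrast 1).
#'
#' @param grid_size Side length of the square phase grid in pixels. Must be
#'   at least twice the rendered frame size so that translated patterns stay
#'   inside the guard band.
#' @param seed Integer seed; the same seed reproduces the same screen.
#' @param frame_size Frame size the screen must support (guard-band check).
#' @return An object of class `"phase_screen"`: a list with `phases`
#'   (grid_size x grid_size matrix), `grid_size` and `seed`.
#' @examples
#' scr <- make_phase_screen(256, seed = 1, frame_size = 128)
#' range(scr$phases)
#' @export
make_phase_screen <- function(grid_size, seed, frame_size = grid_size / 2) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L * frame_size) {
    stop("phase screen grid_size must be at least twice the frame size ",
         "(guard band for shifting)", call. = FALSE)
  }
  phases <- local({
    rs <- .save_rng_state()
    on.exit(.restore_rng_state(rs))
    set.seed(as.integer(seed))
    matrix(stats::runif(grid_size^2, 0, 2 * pi), grid_size, grid_size)
  })
  structure(list(phases = phases, grid_size = grid_size,
                 seed = as.integer(seed)),
            class = "phase_screen")
}

# Complex aperture field: circular pupil of diameter pupil_fraction * N
# carrying the roughness phase. The speckle grain on the rendered field is
# ~ N / (pupil_fraction * N) = 1 / pupil_fraction pixels.
.base_field <- function(screen, pupil_fraction) {
  n <- screen$grid_size
  if (pupil_fraction <= 0 || pupil_fraction > 1) {
    stop("pupil_fraction must be in (0, 1]", call. = FALSE)
  }
  cen <- (n + 1) / 2
  r <- pupil_fraction * n / 2
  idx <- seq_len(n) - cen
  pup <- outer(idx^2, idx^2, "+") <= r^2
  pup * exp(1i * screen$phases)
}

# Full-field speckle intensity translated by `shift` = c(dx, dy) pixels
# (x = column, y = row, both may be fractional) via the transform-domain
# shift property: multiplying the aperture field by a linear phase ramp
# translates the far-field pattern exactly (cyclically).
.render_intensity <- function(base, shift) {
  n <- nrow(base)
  k <- 0:(n - 1)
  ramp_x <- exp(2i * pi * k * shift[1] / n)  # columns
  ramp_y <- exp(2i * pi * k * shift[2] / n)  # rows
  u <- stats::fft(base * (ramp_y %o% ramp_x))
  Re(u)^2 + Im(u)^2
}

.crop_center <- function(m, size) {
  off <- (nrow(m) - size) %/% 2
  m[(off + 1):(off + size), (off + 1):(off + size), drop = FALSE]
}

#' Render one speckle frame
#'
#' Computes the far-field speckle intensity of a circular laser spot over a
#' rough surface: the squared modulus of the Fourier transform of the pupil
#' times `exp(i * phi)`, translated by `shift` through the transform-domain
#' shift property (exact to subpixel precision), cropped to the central
#' `frame_size` pixels, scaled to the detector bit depth, and optionally
#' degraded by Gaussian read noise and Poisson shot noise. At zero noise
#' (and without quantization) the frame obeys fully developed speckle
#' statistics: negative-exponential intensities with contrast 1.
#'
#' @param screen A [make_phase_screen()] object.
#' @param shift Length-2 numeric `c(dx, dy)` in pixels; x = column
#'   (rightward), y = row (downward). May be fractional. Must lie within
#'   the guard band `(grid_size - frame_size) / 2`.
#' @param frame_size Output frame side length in pixels (default 224).
#' @param pupil_fraction Pupil diameter as a fraction of the render field;
#'   controls speckle grain size (~ `1/pupil_fraction` pixels).
#' @param bit_depth Detector bit depth, 8 or 16.
#' @param read_noise_dn Additive Gaussian read noise sigma in DN.
#' @param shot_noise If `TRUE`, Poisson shot noise at unit DN gain.
#' @param target_mean_dn Mean intensity in DN; default 40 (8-bit) or
#'   4000 (16-bit), keeping the exponential tail clear of saturation.
#' @param quantize If `TRUE` (default) round and clip to the bit-depth
#'   range; `FALSE` returns the continuous noiseless-statistics frame.
#' @return A `frame_size` x `frame_size` numeric matrix of intensities (DN).
#' @export
render_frame <- function(screen, shift = c(0, 0), frame_size = 224,
                         pupil_fraction = 0.25, bit_depth = 8,
                         read_noise_dn = 2, shot_noise = FALSE,
                         target_mean_dn = NULL, quantize = TRUE) {
  stopifnot(inherits(screen, "phase_screen"), length(shift) == 2)
  n <- screen$grid_size
  guard <- (n - frame_size) / 2
  if (guard < 0) stop("frame_size exceeds screen grid", call. = FALSE)
  if (any(abs(shift) > guard)) {
    stop(sprintf("shift (%.2f, %.2f) outside guard band +-%g px",
                 shift[1], shift[2], guard), call. = FALSE)
  }
  base <- .base_field(screen, pupil_fraction)
  .finish_frame(.render_intensity(base, shift), base, frame_size, bit_depth,
                read_noise_dn, shot_noise, target_mean_dn, quantize)
}

.finish_frame <- function(intensity, base, frame_size, bit_depth,
                          read_noise_dn, shot_noise, target_mean_dn,
                          quantize) {
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (is.null(target_mean_dn)) {
    target_mean_dn <- if (bit_depth == 8) 40 else 4000
  }
  # Parseval: mean full-field |FFT|^2 equals the pupil pixel count, so the
  # DN scaling is analytic and identical across frames of one video.
  npup <- sum(Mod(base) > 0)
  dn <- .crop_center(intensity, frame_size) * (target_mean_dn / npup)
  if (shot_noise) dn <- matrix(stats::rpois(length(dn), lambda = dn),
                               nrow(dn), ncol(dn))
  if (read_noise_dn > 0) dn <- dn + stats::rnorm(length(dn), 0, read_noise_dn)
  if (quantize) {
    dn <- round(dn)
    dn[dn < 0] <- 0
    dn[dn > 2^bit_depth - 1] <- 2^bit_depth - 1
  }
  dn
}

#' Class-specific tilt-signal parameters
#'
#' Describes the surface-tilt signature a given stimulus class evokes in a
#' given brain region in the synthetic scenario: a sum of sinusoidal
#' vibration components plus a cardiac-like pulse baseline and Gaussian
#' tilt noise, attenuated with sensing distance. The default table gives
#' each smell a distinct pair of component frequencies in 5-60 Hz and
#' scales amplitude by region (amygdala strongest), so class separability
#' and the region ranking are reproducible as a synthetic scenario --
#' they are a modelling choice, not asserted biology. The control class
#' carries no odor components, only the pulse baseline and noise.
#'
#' @param smell One of `"control"`, `"alcohol"`, `"marijuana"`,
#'   `"menthol"`, `"garlic"`.
#' @param region One of `"olfactory_bulb"`, `"hippocampus"`, `"amygdala"`.
#' @param component_freqs,component_amps Override the per-class vibration
#'   components (Hz, and micro-radians of tilt amplitude).
#' @param pulse_rate Cardiac-like baseline rate in Hz.
#' @param pulse_amp Pulse-train tilt amplitude in micro-radians.
#' @param noise_floor Gaussian tilt-noise RMS in micro-radians.
#' @param distance_gain Named numeric map from distance in metres (as a
#'   string) to an amplitude factor.
#' @param amp_scale Global multiplier on all deterministic signal
#'   amplitudes; used for signal-to-noise sweeps.
#' @param y_scale Vertical-axis amplitude relative to horizontal.
#' @return An object of class `"class_signal_params"`.
#' @export
class_signal_params <- function(smell, region,
                                component_freqs = NULL,
                                component_amps = NULL,
                                pulse_rate = 1.8, pulse_amp = 0.3,
                                noise_floor = 0.2,
                                distance_gain = c("0.1" = 1.0, "1" = 0.4),
                                amp_scale = 1, y_scale = 0.6) {
  smell <- match.arg(smell, smell_classes())
  region <- match.arg(region, brain_regions())
  if (is.null(component_freqs)) {
    tab <- list(control   = numeric(0),
                alcohol   = c(8, 35),
                marijuana = c(14, 42),
                menthol   = c(22, 48),
                garlic    = c(28, 56))
    component_freqs <- tab[[smell]]
  }
  if (is.null(component_amps)) {
    rscale <- c(olfactory_bulb = 0.6, hippocampus = 0.35, amygdala = 1.0)
    component_amps <- rep_len(c(1.0, 0.8),
                              length(component_freqs)) * rscale[[region]]
  }
  if (length(component_freqs) != length(component_amps)) {
    stop("component_freqs and component_amps must have equal length",
         call. = FALSE)
  }
  if (any(component_freqs <= 0) || any(component_amps < 0)) {
    stop("component freqs must be positive and amps non-negative",
         call. = FALSE)
  }
  structure(list(smell = smell, region = region,
                 component_freqs = component_freqs,
                 component_amps = component_amps,
                 pulse_rate = pulse_rate, pulse_amp = pulse_amp,
                 noise_floor = noise_floor, distance_gain = distance_gain,
                 amp_scale = amp_scale, y_scale = y_scale),
            class = "class_signal_params")
}

#' @rdname class_signal_params
#' @export
smell_classes <- function() {
  c("control", "alcohol", "marijuana", "menthol", "garlic")
}

#' @rdname class_signal_params
#' @export
brain_regions <- function() {
  c("olfactory_bulb", "hippocampus", "amygdala")
}

.distance_gain <- function(params, distance_m) {
  key <- as.character(distance_m)
  keys <- names(params$distance_gain)
  hit <- which(abs(as.numeric(keys) - distance_m) < 1e-9)
  if (length(hit) == 0) {
    stop("no distance_gain entry for distance ", key, call. = FALSE)
  }
  unname(params$distance_gain[[hit[1]]])
}

#' Generate a surface-tilt time series for one recording
#'
#' Produces per-frame horizontal and vertical surface tilts (micro-radians)
#' as the sum of the class's sinusoidal components (random phases), a
#' periodic cardiac-like pulse train, and Gaussian tilt noise, all scaled
#' by the distance gain. The vertical axis carries the same components at
#' `y_scale` relative amplitude with independent phases.
#'
#' @param params A [class_signal_params()] object.
#' @param duration_s Recording duration in seconds (> 0).
#' @param fps Frame rate in Hz.
#' @param distance_m Sensing distance in metres (selects the gain).
#' @return Object of class `"tilt_trace"`: list with `theta_x`, `theta_y`
#'   (micro-radians, length `round(duration_s * fps)`) and `fps`.
#' @export
tilt_signal <- function(params, duration_s, fps = 200, distance_m = 0.1) {
  stopifnot(inherits(params, "class_signal_params"), duration_s > 0, fps > 0)
  if (any(params$component_freqs >= fps / 2)) {
    stop("component frequency at or above Nyquist (fps/2): aliasing",
         call. = FALSE)
  }
  n <- round(duration_s * fps)
  t <- (0:(n - 1)) / fps
  gain <- .distance_gain(params, distance_m) * params$amp_scale

  one_axis <- function(amp_factor) {
    th <- numeric(n)
    for (j in seq_along(params$component_freqs)) {
      th <- th + params$component_amps[j] * amp_factor *
        sin(2 * pi * params$component_freqs[j] * t + stats::runif(1, 0, 2 * pi))
    }
    if (params$pulse_amp > 0 && params$pulse_rate > 0) {
      phase <- (t * params$pulse_rate) %% 1
      bump <- exp(-0.5 * ((phase - 0.5) / 0.12)^2)
      th <- th + params$pulse_amp * amp_factor * (bump - mean(bump))
    }
    th <- th * gain
    if (params$noise_floor > 0) {
      th <- th + stats::rnorm(n, 0, params$noise_floor * gain)
    }
    th
  }
  structure(list(theta_x = one_axis(1),
                 theta_y = one_axis(params$y_scale),
                 fps = fps),
            class = "tilt_trace")
}

#' Recording protocol
#'
#' Acquisition settings of one simulated recording session: frame geometry,
#' rate, repeats, render-field size (guard band), tilt-to-shift coupling and
#' sensor noise. Defaults follow the experimental protocol the simulator
#' emulates: 224 x 224 frames at 200 FPS, 5-s recordings repeated 4 times,
#' rendered on a 512-px field (guard band +-144 px for 224-px frames).
#'
#' @param duration_s Duration of one repeat in seconds.
#' @param repeats Number of repeats concatenated into a video.
#' @param fps Frame rate (Hz).
#' @param frame_size Frame side length (px).
#' @param field_size Render-field side length (px), >= 2 * frame_size.
#' @param gain_px_per_urad Tilt-to-shift gain g (px per micro-radian);
#'   speckle translation is `g * theta`.
#' @param pupil_fraction Speckle grain control, see [render_frame()].
#' @param bit_depth,read_noise_dn,shot_noise,target_mean_dn Sensor model,
#'   see [render_frame()].
#' @return Object of class `"recording_protocol"`.
#' @export
recording_protocol <- function(duration_s = 5, repeats = 4, fps = 200,
                               frame_size = 224, field_size = 512,
                               gain_px_per_urad = 0.5, pupil_fraction = 0.25,
                               bit_depth = 8, read_noise_dn = 2,
                               shot_noise = FALSE, target_mean_dn = NULL) {
  if (gain_px_per_urad <= 0) {
    stop("tilt-to-shift gain must be positive", call. = FALSE)
  }
  if (field_size < 2 * frame_size) {
    stop("field_size must be at least twice frame_size", call. = FALSE)
  }
  structure(list(duration_s = duration_s, repeats = repeats, fps = fps,
                 frame_size = frame_size, field_size = field_size,
                 gain_px_per_urad = gain_px_per_urad,
                 pupil_fraction = pupil_fraction, bit_depth = bit_depth,
                 read_noise_dn = read_noise_dn, shot_noise = shot_noise,
                 target_mean_dn = target_mean_dn),
            class = "recording_protocol")
}

#' Simulate one speckle video recording
#'
#' Renders a complete speckle video for one (dog, region, smell, distance)
#' cell: draws a phase screen, generates one tilt trace per repeat, maps
#' tilt to speckle translation through the gain `g` (px/micro-radian), and
#' renders every frame. Repeats are independent recordings of the same
#' surface concatenated along time.
#'
#' @param params A [class_signal_params()] object.
#' @param protocol A [recording_protocol()] object.
#' @param distance_m Sensing distance in metres.
#' @param dog_id,video_tag Metadata for the manifest.
#' @param seed Integer seed; the full video is reproducible from it.
#' @param geom Optional [speckle_geometry()] stored as provenance; a
#'   warning is issued if it violates the far-field condition.
#' @return Object of class `"speckle_video"`: list with `frames` (an
#'   `frame_size x frame_size x T` integer-valued array of DN), `fps`,
#'   `dog_id`, `region`, `smell`, `distance_m`, `video_tag`, `bit_depth`,
#'   and ground-truth attributes `truth_tilt` (per-frame theta_x, theta_y)
#'   and `truth_shift_px` (T x 2 matrix of injected shifts).
#' @export
simulate_recording <- function(params, protocol = recording_protocol(),
                               distance_m = 0.1, dog_id = "dog1",
                               video_tag = NULL, seed = 1, geom = NULL) {
  stopifnot(inherits(params, "class_signal_params"),
            inherits(protocol, "recording_protocol"))
  if (!is.null(geom) && !is_far_field(geom)) {
    warning("geometry violates the far-field condition Z2 > D^2/(4 lambda)")
  }
  if (is.null(video_tag)) {
    video_tag <- sprintf("%s_%s_%s_%gm_s%d", dog_id, params$region,
                         params$smell, distance_m, seed)
  }
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs))
  set.seed(as.integer(seed))

  screen <- make_phase_screen(protocol$field_size,
                              seed = sample.int(.Machine$integer.max, 1),
                              frame_size = protocol$frame_size)
  base <- .base_field(screen, protocol$pupil_fraction)
  guard <- (protocol$field_size - protocol$frame_size) / 2

  nper <- round(protocol$duration_s * protocol$fps)
  total <- nper * protocol$repeats
  frames <- array(0L, dim = c(protocol$frame_size, protocol$frame_size, total))
  th_x <- th_y <- numeric(total)
  g <- protocol$gain_px_per_urad

  for (r in seq_len(protocol$repeats)) {
    tilt <- tilt_signal(params, protocol$duration_s, protocol$fps, distance_m)
    idx0 <- (r - 1) * nper
    th_x[idx0 + seq_len(nper)] <- tilt$theta_x
    th_y[idx0 + seq_len(nper)] <- tilt$theta_y
    for (k in seq_len(nper)) {
      sh <- g * c(tilt$theta_x[k], tilt$theta_y[k])
      if (any(abs(sh) > guard)) {
        stop("tilt-induced shift exceeds the render guard band; increase ",
             "field_size or reduce amplitudes/gain", call. = FALSE)
      }
      fr <- .finish_frame(.render_intensity(base, sh), base,
                          protocol$frame_size, protocol$bit_depth,
                          protocol$read_noise_dn, protocol$shot_noise,
                          protocol$target_mean_dn, quantize = TRUE)
      frames[, , idx0 + k] <- as.integer(fr)
    }
  }
  structure(list(frames = frames, fps = protocol$fps, dog_id = dog_id,
                 region = params$region, smell = params$smell,
                 distance_m = distance_m, video_tag = video_tag,
                 bit_depth = protocol$bit_depth, seed = as.integer(seed),
                 truth_tilt = list(theta_x = th_x, theta_y = th_y),
                 truth_shift_px = cbind(x = g * th_x, y = g * th_y)),
            class = "speckle_video")
}

#' @export
print.speckle_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Speckle video '%s': %d frames of %dx%d @ %g FPS\n",
              x$video_tag, d[3], d[1], d[2], x$fps))
  cat(sprintf("  dog %s | region %s | smell %s | distance %g m\n",
              x$dog_id, x$region, x$smell, x$distance_m))
  invisible(x)
}

#' Factorial design for a synthetic dataset
#'
#' @param dogs,regions,smells Character vectors of factor levels.
#' @param distances_m Numeric sensing distances in metres.
#' @param videos_per_cell Videos per (dog, region, smell, distance) cell.
#' @param protocol A [recording_protocol()].
#' @param amp_scale Global signal-amplitude multiplier (SNR sweeps).
#' @return Object of class `"speckle_design"`.
#' @export
speckle_design <- function(dogs = c("lili", "thomas", "tanin", "johny"),
                           regions = brain_regions(),
                           smells = smell_classes(),
                           distances_m = c(0.1, 1.0),
                           videos_per_cell = 3,
                           protocol = recording_protocol(),
                           amp_scale = 1) {
  structure(list(dogs = dogs, regions = regions, smells = smells,
                 distances_m = distances_m,
                 videos_per_cell = videos_per_cell,
                 protocol = protocol, amp_scale = amp_scale),
            class = "speckle_design")
}

#' Generate a full synthetic dataset with manifest
#'
#' Enumerates the factorial cells of a [speckle_design()] in a fixed nested
#' order (dog, region, smell, distance, video index) and simulates one video
#' per cell entry. Per-video seeds are derived from the master seed by a
#' documented counter scheme: `seed_i = (master_seed + 7919 * i) mod
#' (2^31 - 1)` with `i` the enumeration counter, so regeneration from
#' `(design, master_seed)` is exact.
#'
#' @param design A [speckle_design()].
#' @param master_seed Integer master seed.
#' @param out_dir If non-`NULL`, each video is written as a multi-page TIFF
#'   (see [write_speckle_video()]) and dropped from memory; the manifest
#'   gains a `path` column and is also written as `manifest.csv`.
#' @return Object of class `"speckle_dataset"`: list with `manifest` (one
#'   row per video: video_tag, path, dog_id, region, smell, distance_m,
#'   fps, n_frames, seed) and `videos` (named list of
#'   [simulate_recording()] objects, or `NULL` when written to disk).
#' @export
generate_dataset <- function(design, master_seed = 1, out_dir = NULL) {
  stopifnot(inherits(design, "speckle_design"))
  cols <- c("video_tag", "path", "dog_id", "region", "smell",
            "distance_m", "fps", "n_frames", "seed")
  rows <- list()
  videos <- list()
  counter <- 0L
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (dog in design$dogs) for (region in design$regions) {
    for (smell in design$smells) for (dist in design$distances_m) {
      for (v in seq_len(design$videos_per_cell)) {
        counter <- counter + 1L
        vseed <- (as.numeric(master_seed) + 7919 * counter) %%
          (2^31 - 1)
        tag <- sprintf("%s_%s_%s_%gm_v%02d", dog, region, smell, dist, v)
        if (tag %in% names(videos) ||
            tag %in% vapply(rows, `[[`, "", "video_tag")) {
          stop("duplicate video_tag in design: ", tag, call. = FALSE)
        }
        params <- class_signal_params(smell, region,
                                      amp_scale = design$amp_scale)
        vid <- simulate_recording(params, design$protocol, dist,
                                  dog_id = dog, video_tag = tag,
                                  seed = vseed)
        path <- NA_character_
        if (!is.null(out_dir)) {
          path <- file.path(out_dir, paste0(tag, ".tif"))
          write_speckle_video(vid, path)
        } else {
          videos[[tag]] <- vid
        }
        rows[[tag]] <- data.frame(video_tag = tag, path = path,
                                  dog_id = dog, region = region,
                                  smell = smell, distance_m = dist,
                                  fps = design$protocol$fps,
                                  n_frames = dim(vid$frames)[3],
                                  seed = vseed,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
              else as.data.frame(stats::setNames(
                rep(list(character(0)), length(cols)), cols))
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest,
                 videos = if (is.null(out_dir)) videos else NULL),
            class = "speckle_dataset")
}

#' Write / read a speckle video stack
#'
#' Videos are stored as multi-page grayscale TIFF (one page per frame,
#' 8- or 16-bit) or, alternatively, as a raw array-stack `.rds` container;
#' [read_speckle_video()] accepts either.
#'
#' @param video A `speckle_video` object.
#' @param path Output path; extension `.tif`/`.tiff` or `.rds`.
#' @return `write_speckle_video()` returns `path` invisibly;
#'   `read_speckle_video()` returns an H x W x T array of DN.
#' @export
write_speckle_video <- function(video, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    maxdn <- 2^video$bit_depth - 1
    pages <- lapply(seq_len(dim(video$frames)[3]),
                    function(k) video$frames[, , k] / maxdn)
    tiff::writeTIFF(pages, path, bits.per.sample = video$bit_depth)
  } else if (ext == "rds") {
    saveRDS(video$frames, path)
  } else {
    stop("unsupported video container: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_speckle_video
#' @param bit_depth Bit depth used when decoding TIFF pages back to DN.
#' @export
read_speckle_video <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    maxdn <- 2^bit_depth - 1
    arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
    for (k in seq_along(pages)) {
      arr[, , k] <- as.integer(round(pages[[k]] * maxdn))
    }
    arr
  } else if (ext == "rds") {
    readRDS(path)
  } else {
    stop("unsupported video container: .", ext, call. = FALSE)
  }
}

# RNG bookkeeping: functions that take explicit seeds must not disturb the
# caller's RNG stream.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
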