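# Stimulus generators: sinusoidal gratings (flashed and flickering),
# checkerboard white noise, and natural-like videos built from images that are
# jittered and shifted by synthetic gaze traces.
#
# Geometry convention used throughout the package: x rightward, y downward,
# origin at the image centre, all distances in micrometres on the retina;
# pixel_pitch converts pixels to micrometres.

#' Parametric sinusoidal grating specification
#'
#' A grating is parameterized by its spatial frequency `f` (cycles per
#' micrometre), orientation `theta` (radians, in `[0, pi)`) and spatial phase
#' `phi` (radians, in `[0, 2*pi)`).
#'
#' @param f Spatial frequency in cycles/µm (`f >= 0`).
#' @param theta Orientation in radians; wrapped into `[0, pi)`.
#' @param phi Spatial phase in radians; wrapped into `[0, 2*pi)`.
#' @return An object of class `grating_spec` (a list with elements `f`,
#'   `theta`, `phi`).
#' @export
grating_spec <- function(f, theta = 0, phi = 0) {
  stopifnot_finite(c(f, theta, phi), "grating_spec")
  if (any(f < 0)) stop("spatial frequency must be non-negative")
  structure(list(f = f, theta = theta %% pi, phi = phi %% (2 * pi)),
            class = "grating_spec")
}

#' Render a sinusoidal grating as a contrast image
#'
#' Evaluates `C(x, y) = sin(2*pi*f*(x*cos(theta) + y*sin(theta)) + phi)` at the
#' centre coordinate of every pixel, in micrometres.
#'
#' @param spec A [grating_spec()].
#' @param shape Integer vector `c(ny, nx)`: image size in pixels.
#' @param pixel_pitch Pixel side length in µm.
#' @return A `ny x nx` matrix of Weber contrast values in `[-1, 1]`.
#' @export
render_grating <- function(spec, shape, pixel_pitch) {
  stopifnot(length(shape) == 2, all(shape >= 1), pixel_pitch > 0)
  stopifnot_finite(unlist(spec[c("f", "theta", "phi")]), "grating spec")
  co <- pixel_coords(shape, pixel_pitch)
  xg <- matrix(co$x, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  yg <- matrix(co$y, nrow = shape[1], ncol = shape[2])
  sin(2 * pi * spec$f * (xg * cos(spec$theta) + yg * sin(spec$theta)) + spec$phi)
}

#' Grating parameter battery
#'
#' Builds the full factorial table of gratings (frequencies x orientations x
#' phases) together with a presentation schedule, either as 200 ms flashes
#' separated by grey gaps, or as a flicker sequence with one grating per frame
#' in pseudorandom order and a frozen (repeated) test segment.
#'
#' @param frequencies Spatial frequencies (cycles/µm). The classical choice
#'   spans half-periods from 15 to 1200 µm, roughly logarithmically spaced.
#' @param orientations Orientations in radians (equally spaced in `[0, pi)`).
#' @param phases Spatial phases in radians.
#' @param layout `"flashed"` or `"flicker"`.
#' @param n_trials Number of presentations of each grating (flashed layout).
#' @param frame_rate Monitor refresh rate in Hz.
#' @param flash_ms,gap_ms Flash and grey-gap duration for the flashed layout.
#' @param n_frames Total sequence length for the flicker layout.
#' @param frozen_every,frozen_length Flicker layout: insert a frozen segment of
#'   `frozen_length` frames after every `frozen_every` varying frames. The
#'   frozen segment is bit-identical on every repetition.
#' @param seed Integer seed controlling the pseudorandom presentation order.
#' @return A `stimulus_set` with `kind` `"flashed_gratings"` or
#'   `"flicker_gratings"`, a `gratings` table (`f`, `theta`, `phi`), and a
#'   frame-level (flicker) or flash-level (flashed) `schedule`.
#' @export
make_grating_battery <- function(frequencies, orientations, phases,
                                 layout = c("flashed", "flicker"),
                                 n_trials = 1, frame_rate = 85,
                                 flash_ms = 200, gap_ms = 800,
                                 n_frames = NULL,
                                 frozen_every = 1200, frozen_length = 300,
                                 seed = 1) {
  layout <- match.arg(layout)
  if (!length(frequencies) || !length(orientations) || !length(phases))
    stop("at least one frequency, orientation and phase required")
  gr <- expand.grid(phi = phases, theta = orientations, f = frequencies,
                    KEEP.OUT.ATTRS = FALSE)
  gr <- gr[, c("f", "theta", "phi")]
  gr$grating_id <- seq_len(nrow(gr))
  if (layout == "flashed") {
    flash_frames <- round(flash_ms / 1000 * frame_rate)
    gap_frames <- round(gap_ms / 1000 * frame_rate)
    order_ids <- with_seed(derive_seed(seed, 17L), {
      unlist(lapply(seq_len(n_trials), function(t) sample(nrow(gr))))
    })
    schedule <- data.frame(
      flash = seq_along(order_ids),
      grating_id = order_ids,
      trial = rep(seq_len(n_trials), each = nrow(gr)),
      onset_frame = (seq_along(order_ids) - 1L) * (flash_frames + gap_frames) + 1L
    )
    out <- list(kind = "flashed_gratings", gratings = gr, schedule = schedule,
                frame_rate = frame_rate, flash_frames = flash_frames,
                gap_frames = gap_frames, n_trials = n_trials, seed = seed)
  } else {
    if (is.null(n_frames)) n_frames <- 10L * nrow(gr)
    frozen_ids <- with_seed(derive_seed(seed, 23L),
                            sample(nrow(gr), frozen_length, replace = TRUE))
    ids <- integer(0); segment <- integer(0)
    rng_seed <- derive_seed(seed, 29L)
    k <- 0L
    while (length(ids) < n_frames) {
      k <- k + 1L
      varying <- with_seed(derive_seed(rng_seed, k),
                           sample(nrow(gr), frozen_every, replace = TRUE))
      ids <- c(ids, varying, frozen_ids)
      segment <- c(segment, rep(0L, frozen_every), rep(k, frozen_length))
    }
    ids <- ids[seq_len(n_frames)]; segment <- segment[seq_len(n_frames)]
    schedule <- data.frame(frame = seq_len(n_frames), grating_id = ids,
                           frozen_cycle = segment)
    out <- list(kind = "flicker_gratings", gratings = gr, schedule = schedule,
                frame_rate = frame_rate, n_trials = 1L, seed = seed)
  }
  structure(out, class = "stimulus_set")
}

#' Binary checkerboard white-noise stimulus
#'
#' Spatiotemporal binary white noise (100% contrast) on a checkerboard layout
#' of flickering squares. Frames are stored at stixel resolution; the stixel
#' side in µm is recorded as the effective pixel pitch.
#'
#' @param square_size_um Stixel side length in µm (must be an integer multiple
#'   of `pixel_pitch`).
#' @param pixel_pitch Monitor pixel side in µm.
#' @param shape Number of stixels, `c(ny, nx)`.
#' @param update_rate Stimulus update rate in Hz.
#' @param duration_s Duration of the varying (training) part in seconds.
#' @param seed Integer seed; regeneration is bit-identical.
#' @param frozen_test_s Optional duration of a frozen test sequence appended
#'   after the training part (regenerated from the seed alone).
#' @return A `stimulus_set` of kind `"checkerboard"` with a
#'   `frames` array of dimension `n_frames x ny x nx` containing ±1 contrast,
#'   and a `schedule` marking training vs frozen test frames.
#' @export
make_checkerboard <- function(square_size_um = 30, pixel_pitch = 7.5,
                              shape = c(24, 24), update_rate = 30,
                              duration_s = 60, seed = 1, frozen_test_s = 0) {
  if (abs(square_size_um / pixel_pitch - round(square_size_um / pixel_pitch)) > 1e-9)
    stop("square size must be an integer multiple of the pixel pitch")
  n_train <- round(duration_s * update_rate)
  n_test <- round(frozen_test_s * update_rate)
  frames <- array(0, dim = c(n_train + n_test, shape[1], shape[2]))
  if (n_train > 0)
    frames[seq_len(n_train), , ] <- with_seed(
      derive_seed(seed, 101L),
      array(sample(c(-1, 1), n_train * prod(shape), replace = TRUE),
            dim = c(n_train, shape[1], shape[2])))
  if (n_test > 0)
    frames[n_train + seq_len(n_test), , ] <- with_seed(
      derive_seed(seed, 103L),
      array(sample(c(-1, 1), n_test * prod(shape), replace = TRUE),
            dim = c(n_test, shape[1], shape[2])))
  schedule <- data.frame(frame = seq_len(n_train + n_test),
                         segment = rep(c("train", "test"), c(n_train, n_test)))
  structure(list(kind = "checkerboard", frames = frames, schedule = schedule,
                 pixel_pitch = square_size_um, square_size_um = square_size_um,
                 frame_rate = update_rate, seed = seed),
            class = "stimulus_set")
}

#' Synthetic natural-like images (contrast-modulated 1/f noise)
#'
#' Generates grayscale contrast images with an approximately 1/f amplitude
#' spectrum, standardized to a target RMS contrast and clipped to `[-1, 1]`.
#' A smooth multiplicative lognormal envelope (optional, on by default)
#' makes local contrast patchy, emulating the strong non-stationarity of
#' photographic natural scenes — regions of near-uniform luminance next to
#' high-contrast texture — which a plain Gaussian 1/f field lacks and which
#' spatial-contrast analyses rely on. The study's image sets had 38-45% RMS
#' contrast. User-supplied images in the same Weber-contrast convention can
#' be used anywhere these images can.
#'
#' @param n Number of images.
#' @param shape Image size in pixels `c(ny, nx)`.
#' @param rms_contrast Target standard deviation of pixel contrast.
#' @param envelope_strength Log-SD of the contrast envelope (0 disables it).
#' @param envelope_scale_frac Spatial scale of the envelope as a fraction of
#'   the image side (correlation length of local contrast patches).
#' @param seed Integer seed.
#' @return A list of `ny x nx` contrast matrices.
#' @export
make_natural_images <- function(n, shape = c(96, 96), rms_contrast = 0.45,
                                envelope_strength = 0.8,
                                envelope_scale_frac = 0.25, seed = 1) {
  ny <- shape[1]; nx <- shape[2]
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- 1 / pmax(fr, 1 / max(ny, nx))
  amp[1, 1] <- 0  # zero-mean
  env_amp <- exp(-(fr * max(ny, nx) * envelope_scale_frac)^2)
  env_amp[1, 1] <- 0
  lapply(seq_len(n), function(i) {
    white <- with_seed(derive_seed(seed, 211L, i),
                       matrix(stats::rnorm(ny * nx), ny, nx))
    img <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (ny * nx)
    if (envelope_strength > 0) {
      wenv <- with_seed(derive_seed(seed, 213L, i),
                        matrix(stats::rnorm(ny * nx), ny, nx))
      g <- Re(stats::fft(stats::fft(wenv) * env_amp, inverse = TRUE)) / (ny * nx)
      env <- exp(envelope_strength * g / stats::sd(g))
      img <- img * env
    }
    # iterate scaling and clipping so the delivered (post-clip) RMS contrast
    # matches the target despite the heavy-tailed envelope
    for (it in 1:3) img <- clamp(img / stats::sd(img) * rms_contrast, -1, 1)
    img
  })
}

#' Synthetic gaze model
#'
#' Parameters of the synthetic gaze traces used by [make_gaze_video()]:
#' fixational jitter amplitude, saccade count and amplitude per 1 s image
#' presentation. Velocity-related quantities can be converted to deg/s via the
#' retinal magnification (100 µm/deg marmoset, 31 µm/deg mouse).
#'
#' @param jitter_sd_um Per-frame SD of fixational jitter steps (µm).
#' @param saccades_per_image Number of intra-image saccades.
#' @param saccade_amp_um Range `c(min, max)` of saccade amplitudes (µm),
#'   executed within a single frame step.
#' @param axis `"free"` for 2-D gaze or an angle set in degrees (for example
#'   `c(0, 45, 90, 135)`) from which a 1-D gaze axis is drawn per image.
#' @param resample_axis_per_trial For 1-D gaze: whether the axis is resampled
#'   on every trial (`TRUE`) or fixed per image (`FALSE`, default).
#' @return A list of class `gaze_model`.
#' @export
gaze_model <- function(jitter_sd_um = 2, saccades_per_image = 1,
                       saccade_amp_um = c(100, 300), axis = "free",
                       resample_axis_per_trial = FALSE) {
  structure(list(jitter_sd_um = jitter_sd_um,
                 saccades_per_image = saccades_per_image,
                 saccade_amp_um = saccade_amp_um, axis = axis,
                 resample_axis_per_trial = resample_axis_per_trial),
            class = "gaze_model")
}

#' Natural-like video from jittered images
#'
#' Builds a video in which each image is shown for a fixed duration (1 s by
#' default) and displaced frame-by-frame according to a synthetic gaze trace
#' containing fixational jitter and saccades. Displacement is applied by
#' nearest-pixel translation against an edge-padded copy of each image; the
#' ground-truth saccade frames are recorded for round-trip testing of the
#' fixation detector.
#'
#' @param images List of contrast matrices (same shape), e.g. from
#'   [make_natural_images()].
#' @param gaze Gaze parameters from [gaze_model()].
#' @param frame_rate Video refresh rate (Hz).
#' @param image_duration_s Presentation time per image (seconds).
#' @param pixel_pitch Pixel side in µm.
#' @param crop Output frame size in pixels `c(ny, nx)`; must leave enough
#'   padding in the source images to absorb the gaze displacement.
#' @param overflow What to do when a gaze trace exceeds the padding:
#'   `"rescale"` (default) shrinks that image's trace to fit, `"error"`
#'   rejects the configuration.
#' @param seed Integer seed.
#' @return A `stimulus_set` of kind `"video"` with a frame-level `schedule`
#'   (`image_id`, displacement `dx_um`/`dy_um`, `transition` flag) and a
#'   `gaze` element of class `gaze_trace` holding positions (µm) and
#'   ground-truth `saccade_frames`. Frames are materialized lazily with
#'   [video_frame()].
#' @export
make_gaze_video <- function(images, gaze = gaze_model(), frame_rate = 85,
                            image_duration_s = 1, pixel_pitch = 7.5,
                            crop = NULL, overflow = c("rescale", "error"),
                            seed = 1) {
  overflow <- match.arg(overflow)
  stopifnot(length(images) >= 1)
  sh <- dim(images[[1]])
  if (!all(vapply(images, function(im) identical(dim(im), sh), logical(1))))
    stop("all images must share the same shape")
  if (is.null(crop)) crop <- sh - 2 * ceiling(60 / pixel_pitch)
  pad <- (sh - crop) %/% 2
  if (any(pad < 0)) stop("crop larger than source images")
  fpi <- round(image_duration_s * frame_rate)
  n_img <- length(images)
  n_frames <- n_img * fpi
  pos <- matrix(0, n_frames, 2)
  saccade_frames <- integer(0)
  for (i in seq_len(n_img)) {
    s_img <- derive_seed(seed, 311L, i)
    steps <- with_seed(s_img, matrix(stats::rnorm(fpi * 2, sd = gaze$jitter_sd_um),
                                     fpi, 2))
    if (!identical(gaze$axis, "free")) {
      ang <- with_seed(derive_seed(s_img, 1L),
                       sample(gaze$axis, 1)) * pi / 180
      amp1 <- with_seed(derive_seed(s_img, 2L), stats::rnorm(fpi, sd = gaze$jitter_sd_um))
      steps <- cbind(amp1 * cos(ang), amp1 * sin(ang))
    }
    if (gaze$saccades_per_image > 0 && fpi > 4) {
      k <- gaze$saccades_per_image
      at <- with_seed(derive_seed(s_img, 3L),
                      sort(sample(3:(fpi - 2), k)))
      amp <- with_seed(derive_seed(s_img, 4L),
                       stats::runif(k, gaze$saccade_amp_um[1], gaze$saccade_amp_um[2]))
      dir <- with_seed(derive_seed(s_img, 5L), stats::runif(k, 0, 2 * pi))
      for (j in seq_len(k)) {
        steps[at[j], ] <- steps[at[j], ] + amp[j] * c(cos(dir[j]), sin(dir[j]))
        # pull back towards centre so the trace stays within padding
        steps[min(at[j] + 1, fpi), ] <- steps[min(at[j] + 1, fpi), ] -
          0.5 * amp[j] * c(cos(dir[j]), sin(dir[j]))
      }
      saccade_frames <- c(saccade_frames, (i - 1L) * fpi + at)
    }
    p <- apply(steps, 2, cumsum)
    p <- sweep(p, 2, colMeans(p))  # centre the trace within the image
    lim <- 0.98 * min(pad) * pixel_pitch
    if (max(abs(p)) > lim) {
      if (overflow == "error")
        stop(sprintf("gaze displacement (%.0f um) exceeds image padding (%.0f um)",
                     max(abs(p)), min(pad) * pixel_pitch))
      p <- p * (lim / max(abs(p)))
    }
    pos[(i - 1L) * fpi + seq_len(fpi), ] <- p
  }
  schedule <- data.frame(
    frame = seq_len(n_frames),
    image_id = rep(seq_len(n_img), each = fpi),
    dx_um = pos[, 1], dy_um = pos[, 2],
    transition = rep(c(TRUE, rep(FALSE, fpi - 1L)), n_img)
  )
  trace <- structure(list(positions = pos, frame_rate = frame_rate,
                          saccade_frames = sort(saccade_frames)),
                     class = "gaze_trace")
  structure(list(kind = "video", images = images, schedule = schedule,
                 gaze = trace, crop = crop, pad = pad,
                 pixel_pitch = pixel_pitch, frame_rate = frame_rate,
                 frames_per_image = fpi, seed = seed),
            class = "stimulus_set")
}

#' Materialize one video frame
#'
#' Crops the scheduled image at its nearest-pixel gaze displacement.
#'
#' @param video A `stimulus_set` of kind `"video"`.
#' @param t Frame index (1-based).
#' @return Contrast matrix of the configured crop size.
#' @export
video_frame <- function(video, t) {
  stopifnot(inherits(video, "stimulus_set"), video$kind == "video")
  sc <- video$schedule[t, ]
  im <- video$images[[sc$image_id]]
  dy <- round(sc$dy_um / video$pixel_pitch)
  dx <- round(sc$dx_um / video$pixel_pitch)
  ny <- video$crop[1]; nx <- video$crop[2]
  r0 <- video$pad[1] + dy; c0 <- video$pad[2] + dx
  ri <- clamp(r0 + seq_len(ny), 1, nrow(im))
  ci <- clamp(c0 + seq_len(nx), 1, ncol(im))  # edge padding by clamping
  im[ri, ci, drop = FALSE]
}

#' Flashed natural-image stimulus
#'
#' Presents a list of images as 200 ms flashes separated by grey gaps,
#' in randomized order, with a given number of trials.
#'
#' @inheritParams make_gaze_video
#' @param n_trials Trials per image.
#' @return A `stimulus_set` of kind `"flashed_images"` with a flash-level
#'   schedule.
#' @export
make_flashed_images <- function(images, n_trials = 8, pixel_pitch = 7.5,
                                frame_rate = 85, seed = 1) {
  n <- length(images)
  order_ids <- with_seed(derive_seed(seed, 401L),
                         unlist(lapply(seq_len(n_trials), function(t) sample(n))))
  schedule <- data.frame(flash = seq_along(order_ids), image_id = order_ids,
                         trial = rep(seq_len(n_trials), each = n))
  structure(list(kind = "flashed_images", images = images, schedule = schedule,
                 pixel_pitch = pixel_pitch, frame_rate = frame_rate, seed = seed),
            class = "stimulus_set")
}
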