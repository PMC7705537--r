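#' Specification of one synthetic whisker
#'
#' A synthetic whisker rotates about a fixed hidden pivot located
#' `pivot_depth` px behind the snout line at along-line position `pivot_rho`.
#' Its base angle follows `theta(t) = rest_angle + amplitude *
#' sin(2*pi*frequency*t + phase)` and its base position is tied to the angle
#' by the pivot geometry `rho = pivot_depth * cot(theta) + pivot_rho`, so the
#' ground-truth (rho, theta) samples of each whisker lie exactly on a line in
#' (cot(theta), rho) space.
#'
#' @param pivot_rho along-line position of the pivot foot (px)
#' @param pivot_depth distance of the pivot behind the snout line (px, > 0)
#' @param rest_angle resting base angle (radians, in (0, pi))
#' @param amplitude whisking amplitude (radians)
#' @param frequency whisking frequency (Hz); mice whisk at roughly 5-30 Hz
#' @param phase phase offset (radians)
#' @param bend,bend_amp bending coefficient baseline and modulation (px^-1);
#'   `b(t) = bend + bend_amp * sin(2*pi*frequency*t + phase + pi/2)`
#' @param length base-to-tip distance L (px)
#' @param width rendered full width at half maximum of the Gaussian intensity
#'   profile (px)
#' @param contrast fractional attenuation of the backlight at the centerline
#'   (0-1)
#' @return a `whisker_spec` list
#' @export
whisker_spec <- function(pivot_rho, pivot_depth, rest_angle,
                         amplitude = deg2rad(12), frequency = 8, phase = 0,
                         bend = 1e-3, bend_amp = 0, length = 180,
                         width = 2.5, contrast = 0.7) {
  stopifnot(pivot_depth > 0, rest_angle > 0, rest_angle < pi, length > 0,
            width > 0, contrast > 0, contrast <= 1)
  structure(list(pivot_rho = pivot_rho, pivot_depth = pivot_depth,
                 rest_angle = rest_angle, amplitude = amplitude,
                 frequency = frequency, phase = phase, bend = bend,
                 bend_amp = bend_amp, length = length, width = width,
                 contrast = contrast),
            class = "whisker_spec")
}

#' Synthetic scene configuration
#'
#' Describes a backlit high-speed recording of a whisking snout: a bright
#' static background with mild texture, a dark snout silhouette below the
#' snout line with short jittering fur fragments near the edge, and
#' `length(whiskers)` dark Gaussian-profile whiskers anchored at hidden
#' pivots. Everything is reproducible from `seed`.
#'
#' @param shape image dimensions `c(rows, cols)` in px
#' @param fps frames per second
#' @param n_frames number of frames
#' @param snout a [snout_line]; defaults to a vertical line with whiskers on
#'   the +x side
#' @param whiskers list of [whisker_spec]
#' @param background_level backlight intensity (0-1)
#' @param texture_amp amplitude of the static background texture
#' @param snout_level intensity of the snout silhouette
#' @param noise_sd per-pixel Gaussian sensor noise sd (intensity units)
#' @param fur list: `n` fragments, `max_len` px, `contrast`, `width` (FWHM px),
#'   `jitter_sd` per-frame positional jitter in px (jitter makes fur survive
#'   background subtraction, as moving fur does in real videos)
#' @param occlusions list of `list(whisker=, frames=)` entries, see
#'   [script_occlusion()]
#' @param seed integer RNG seed
#' @return a `scene_config` list
#' @export
scene_config <- function(shape = c(480, 512), fps = 1000, n_frames = 100,
                         snout = NULL, whiskers = list(),
                         background_level = 0.85, texture_amp = 0.02,
                         snout_level = 0.12, noise_sd = 0.006,
                         fur = list(n = 40, max_len = 12, contrast = 0.18,
                                    width = 1.4, jitter_sd = 0.4),
                         occlusions = list(), seed = 1L) {
  if (is.null(snout))
    snout <- snout_line(c(80, 1), c(80, shape[1]), side_point = c(200, 1))
  stopifnot(inherits(snout, "snout_line"), n_frames >= 1, fps > 0)
  for (w in whiskers) {
    stopifnot(inherits(w, "whisker_spec"))
    if (w$frequency <= 0 || w$frequency >= fps / 2)
      stop("whisking frequency must lie in (0, fps/2)")
  }
  structure(list(shape = as.integer(shape), fps = fps,
                 n_frames = as.integer(n_frames), snout = snout,
                 whiskers = whiskers, background_level = background_level,
                 texture_amp = texture_amp, snout_level = snout_level,
                 noise_sd = noise_sd, fur = fur, occlusions = occlusions,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Script a transient occlusion
#'
#' Marks a whisker as not rendered (and not visible in the ground truth) for
#' a range of frames, emulating a whisker hidden behind others.
#'
#' @param cfg a [scene_config]
#' @param whisker whisker index
#' @param frames integer frame range (1-based)
#' @return the modified configuration
#' @export
script_occlusion <- function(cfg, whisker, frames) {
  stopifnot(inherits(cfg, "scene_config"))
  frames <- as.integer(frames)
  if (length(frames) == 0) return(cfg)
  stopifnot(whisker >= 1, whisker <= length(cfg$whiskers),
            all(frames >= 1), all(frames <= cfg$n_frames))
  cfg$occlusions <- c(cfg$occlusions,
                      list(list(whisker = as.integer(whisker),
                                frames = frames)))
  cfg
}

fwhm_to_sd <- function(w) w / (2 * sqrt(2 * log(2)))

## ground-truth parameters of whisker k at frame i (1-based)
truth_params <- function(cfg, k, frame) {
  w <- cfg$whiskers[[k]]
  t <- (frame - 1) / cfg$fps
  ph <- 2 * pi * w$frequency * t + w$phase
  theta <- w$rest_angle + w$amplitude * sin(ph)
  rho <- w$pivot_depth * cos(theta) / sin(theta) + w$pivot_rho
  b <- w$bend + w$bend_amp * sin(ph + pi / 2)
  list(rho = rho, theta = theta, b = b, L = w$length)
}

#' Generate a synthetic whisker scene
#'
#' Builds the static background, snout mask and fur layout, and the full
#' per-frame ground truth. Frames are rendered lazily through
#' [scene_frame()] so long videos never have to be held in memory.
#'
#' @param cfg a [scene_config]
#' @return object of class `whisker_scene` with fields `cfg`, `background`
#'   (static background image including texture), `snout_mask` (logical
#'   matrix), `truth` (data frame: `frame`, `whisker`, `rho`, `theta`, `b`,
#'   `L`, `visible`), and `pivots` (data frame of the true `pivot_rho`,
#'   `pivot_depth` per whisker)
#' @examples
#' cfg <- scene_config(shape = c(120, 160), n_frames = 4,
#'   whiskers = list(whisker_spec(60, 40, pi / 2, length = 60)))
#' sc <- generate_scene(cfg)
#' fr <- scene_frame(sc, 1)
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  ## static textured background
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr), nc), nr, nc)
  bg <- cfg$background_level +
    cfg$texture_amp * sin(2 * pi * xg / 97) * cos(2 * pi * yg / 71)
  ## snout region: non-whisker side of the line
  sd_grid <- (xg - cfg$snout$p0[1]) * cfg$snout$n[1] +
             (yg - cfg$snout$p0[2]) * cfg$snout$n[2]
  snout_mask <- sd_grid < 0
  ## static fur layout (jittered per frame at render time)
  fur <- withr::with_seed(frame_seed(cfg$seed, 0), {
    lapply(seq_len(cfg$fur$n), function(i) {
      rho <- runif(1, 5, cfg$snout$length - 5)
      base <- drop(snout_point(cfg$snout, rho))
      ang <- runif(1, 0.25 * pi, 0.75 * pi)
      len <- runif(1, 3, cfg$fur$max_len)
      dirv <- cos(ang) * cfg$snout$u + sin(ang) * cfg$snout$n
      s <- seq(0, len, by = 0.5)
      cbind(base[1] + s * dirv[1], base[2] + s * dirv[2])
    })
  })
  ## ground truth table
  occl <- matrix(FALSE, cfg$n_frames, max(1, length(cfg$whiskers)))
  for (oc in cfg$occlusions) occl[oc$frames, oc$whisker] <- TRUE
  truth <- do.call(rbind, lapply(seq_len(cfg$n_frames), function(i) {
    if (length(cfg$whiskers) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(cfg$whiskers), function(k) {
      p <- truth_params(cfg, k, i)
      data.frame(frame = i, whisker = k, rho = p$rho, theta = p$theta,
                 b = p$b, L = p$L, visible = !occl[i, k])
    }))
  }))
  if (is.null(truth))
    truth <- data.frame(frame = integer(), whisker = integer(),
                        rho = numeric(), theta = numeric(), b = numeric(),
                        L = numeric(), visible = logical())
  pivots <- if (length(cfg$whiskers)) {
    data.frame(whisker = seq_along(cfg$whiskers),
               pivot_rho = vapply(cfg$whiskers, `[[`, 0, "pivot_rho"),
               pivot_depth = vapply(cfg$whiskers, `[[`, 0, "pivot_depth"))
  } else data.frame(whisker = integer(), pivot_rho = numeric(),
                    pivot_depth = numeric())
  structure(list(cfg = cfg, background = bg, snout_mask = snout_mask,
                 fur = fur, truth = truth, pivots = pivots),
            class = "whisker_scene")
}

#' Render one frame of a synthetic scene
#'
#' Whiskers and fur attenuate the backlight multiplicatively with an analytic
#' Gaussian cross-section (no rasterization aliasing), the snout region is
#' set to its silhouette level, and seeded Gaussian sensor noise is added.
#' Rendering frame `i` twice yields bit-identical pixels.
#'
#' @param scene a `whisker_scene`
#' @param i frame index (1-based)
#' @return intensity matrix in `[0, 1]`
#' @export
scene_frame <- function(scene, i) {
  stopifnot(inherits(scene, "whisker_scene"), i >= 1, i <= scene$cfg$n_frames)
  cfg <- scene$cfg
  canvas <- scene$background + 0   # fresh copy
  withr::with_seed(frame_seed(cfg$seed, i), {
    ## jittered fur
    if (cfg$fur$n > 0) {
      for (f in scene$fur) {
        jit <- rnorm(2, 0, cfg$fur$jitter_sd)
        pts <- cbind(f[, 1] + jit[1], f[, 2] + jit[2])
        cpp_render_ridge(canvas, pts, fwhm_to_sd(cfg$fur$width),
                         cfg$fur$contrast)
      }
    }
    ## whiskers
    tr <- scene$truth[scene$truth$frame == i, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      if (!tr$visible[r]) next
      w <- cfg$whiskers[[tr$whisker[r]]]
      p <- list(rho = tr$rho[r], theta = tr$theta[r], b = tr$b[r], L = tr$L[r])
      n_samp <- max(32L, ceiling(4 * p$L))
      pts <- whisker_curve(p, cfg$snout, n_samples = n_samp)
      cpp_render_ridge(canvas, pts, fwhm_to_sd(w$width), w$contrast)
    }
    canvas[scene$snout_mask] <- cfg$snout_level
    if (cfg$noise_sd > 0)
      canvas <- canvas + matrix(rnorm(length(canvas), 0, cfg$noise_sd),
                                nrow(canvas), ncol(canvas))
  })
  pmin(pmax(canvas, 0), 1)
}

#' Analytic ground-truth centerline of one whisker in one frame
#'
#' @param scene a `whisker_scene`
#' @param frame,whisker indices
#' @param n_samples number of samples
#' @return `n_samples` x 2 matrix of image points
#' @export
scene_centerline <- function(scene, frame, whisker, n_samples = 200) {
  tr <- scene$truth
  row <- tr[tr$frame == frame & tr$whisker == whisker, ]
  stopifnot(nrow(row) == 1)
  whisker_curve(list(rho = row$rho, theta = row$theta, b = row$b, L = row$L),
                scene$cfg$snout, n_samples = n_samples)
}

#' Frames where two whiskers' centerlines intersect
#'
#' Checks, per frame, whether the sampled centerlines of the two whiskers
#' approach within `tol` px (both visible).
#'
#' @param scene a `whisker_scene`
#' @param pair integer vector of two whisker indices
#' @param tol crossing distance tolerance in px
#' @param n_samples centerline samples per whisker
#' @return integer vector of crossing frames
#' @export
scene_crossings <- function(scene, pair, tol = 1, n_samples = 80) {
  stopifnot(length(pair) == 2)
  out <- integer(0)
  for (i in seq_len(scene$cfg$n_frames)) {
    tr <- scene$truth[scene$truth$frame == i, ]
    if (!all(tr$visible[match(pair, tr$whisker)])) next
    a <- scene_centerline(scene, i, pair[1], n_samples)
    b <- scene_centerline(scene, i, pair[2], n_samples)
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    if (min(d2) <= tol^2) out <- c(out, i)
  }
  out
}

#' Preset benchmark scenes
#'
#' `"benchmark-B"` is the default tracking benchmark: 10 whiskers on a
#' 480 x 512 px frame at a 1,000 fps-equivalent frame rate, 2,000 frames,
#' with two whisker pairs phased to cross during the run and one 20-frame
#' occlusion of whisker 5, seed 42.
#'
#' @param preset preset name (currently `"benchmark-B"`)
#' @param seed RNG seed
#' @param n_frames optionally override the number of frames (a shortened
#'   prefix of the same scene; whisker layout and seeds are unchanged)
#' @return a [scene_config]
#' @export
benchmark_scene_config <- function(preset = "benchmark-B", seed = 42L,
                                   n_frames = 2000L) {
  preset <- match.arg(preset)
  snout <- snout_line(c(80, 1), c(80, 480), side_point = c(300, 240))
  rest <- deg2rad(seq(105, 75, length.out = 10))
  pivot_rho <- seq(120, 370, length.out = 10)
  amp <- deg2rad(c(10, 12, 11, 11, 12, 12, 10, 12, 11, 10))
  ## phases: coherent whisking, with whiskers 4 and 8 offset just enough
  ## that each briefly crosses its nearest neighbor once per whisk cycle
  ## (relative angle amplitude ~5 deg vs. ~3.3 deg rest-angle spacing)
  phase <- rep(0, 10); phase[4] <- 0.45; phase[8] <- 0.45
  len <- c(200, 230, 250, 240, 260, 250, 240, 230, 210, 190)
  whiskers <- lapply(1:10, function(k)
    whisker_spec(pivot_rho = pivot_rho[k], pivot_depth = 40,
                 rest_angle = rest[k], amplitude = amp[k], frequency = 8,
                 phase = phase[k], bend = 8e-4, bend_amp = 3e-4,
                 length = len[k], width = 2.5, contrast = 0.7))
  cfg <- scene_config(shape = c(480, 512), fps = 1000,
                      n_frames = as.integer(n_frames), snout = snout,
                      whiskers = whiskers, seed = as.integer(seed))
  if (n_frames >= 1020)
    cfg <- script_occlusion(cfg, 5, 1001:1020)
  cfg
}
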