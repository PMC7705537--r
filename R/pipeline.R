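## configuration helpers: run-config blocks -> module config objects

cluster_config_from <- function(cc) {
  cluster_config(method = cc$method, dbscan_eps = cc$dbscan_eps,
                 dbscan_min_pts = cc$dbscan_min_pts,
                 steger_angle_tol = deg2rad(cc$steger_angle_tol_deg),
                 stitch_fit_len = cc$stitch_fit_len,
                 stitch_max_dist = cc$stitch_max_dist,
                 stitch_max_gap = cc$stitch_max_gap,
                 stitch_max_angle = deg2rad(cc$stitch_max_angle_deg),
                 min_whisker_len = cc$min_whisker_len,
                 snout_attach_dist = cc$snout_attach_dist)
}

tracker_config_from <- function(tc) {
  tracker_config(bootstrap_len = tc$bootstrap_len, s = tc$s, W = tc$W,
                 max_train_per_class = tc$max_train_per_class,
                 min_train_samples = tc$min_train_samples,
                 assign_max_cost = tc$assign_max_cost,
                 max_dtheta = deg2rad(tc$max_dtheta_deg),
                 max_drho = tc$max_drho, max_coast = tc$max_coast,
                 svm_cost = tc$svm_cost)
}

#' Detect and parameterize whiskers in one cleaned frame
#'
#' Centerline detection, clustering and per-cluster model fitting; the
#' per-frame detection stage of the pipeline.
#'
#' @param cleaned preprocessed intensity matrix (whiskers bright)
#' @param snout a [snout_line]
#' @param ccfg a [cluster_config]
#' @param sigma derivative scale (px)
#' @param min_strength ridge-strength threshold (see
#'   [detect_centerline_points()])
#' @param fit_cfg list with `max_iter`, `tol`, `max_rms` (fits whose
#'   root-mean-square residual exceeds `max_rms` px are rejected — typically
#'   clusters that merged two crossing whiskers)
#' @return data frame of detections: `rho`, `theta`, `b`, `L`, `rss`; only
#'   converged, snout-connected fits with `theta` inside (0, pi) are kept
#' @export
detect_whiskers <- function(cleaned, snout, ccfg = cluster_config(),
                            sigma = 1.5, min_strength = NULL,
                            fit_cfg = list(max_iter = 100, tol = 1e-8,
                                           max_rms = 1)) {
  derivs <- compute_derivatives(cleaned, sigma)
  pts <- detect_centerline_points(derivs, min_strength)
  clusters <- cluster_whiskers(pts, ccfg, snout, dims = dim(cleaned))
  rows <- list()
  for (cl in clusters) {
    if (nrow(cl$points) < 5) next
    if (abs(snout_dist(snout, cl$base_point)) > ccfg$snout_attach_dist) next
    p <- tryCatch(
      fit_whisker(cl, snout, max_iter = fit_cfg$max_iter, tol = fit_cfg$tol),
      error = function(e) NULL)
    if (is.null(p) || !p$valid) next
    if (p$theta <= 1e-3 || p$theta >= pi - 1e-3) next
    max_rms <- if (is.null(fit_cfg$max_rms)) Inf else fit_cfg$max_rms
    if (sqrt(p$rss / nrow(cl$points)) > max_rms) next
    rows[[length(rows) + 1]] <-
      data.frame(rho = p$rho, theta = p$theta, b = p$b, L = p$L, rss = p$rss)
  }
  if (length(rows) == 0)
    return(data.frame(rho = numeric(), theta = numeric(), b = numeric(),
                      L = numeric(), rss = numeric()))
  do.call(rbind, rows)
}

#' Run the full tracking pipeline
#'
#' Background extraction, per-frame cleaning, centerline detection,
#' clustering, parameter fitting and identity tracking. Frames come either
#' from a synthetic scene (rendered lazily) or from the video source in the
#' configuration. Deterministic given configuration and seed.
#'
#' @param config run configuration (see [default_run_config()])
#' @param scene optional `whisker_scene`; overrides `config$source$path`
#' @param progress print a note every `progress` frames; 0 = silent
#' @return list of class `whisker_run`: `trace` (trace table), `tracks` (the
#'   full `whisker_tracks` object), `n_frames`, `background`, `config`;
#'   traces are written to `config$output$dir` when set
#' @export
run_pipeline <- function(config = default_run_config(), scene = NULL,
                         progress = 0) {
  set.seed(config$seed %% 2147483647)
  if (!is.null(scene)) {
    stopifnot(inherits(scene, "whisker_scene"))
    n_frames <- scene$cfg$n_frames
    get_frame <- function(i) scene_frame(scene, i)
    snout <- scene$cfg$snout
    fps <- scene$cfg$fps
  } else {
    if (is.null(config$source$path)) stop("no video source configured")
    frames <- read_video(config$source$path)
    n_frames <- length(frames)
    get_frame <- function(i) {
      f <- frames[[i]]
      if (isTRUE(config$source$invert)) 1 - f else f
    }
    snout <- snout_line(config$snout$p0, config$snout$p1,
                        side_point = config$snout$side)
    fps <- config$fps
  }
  ccfg <- cluster_config_from(config$cluster)
  tcfg <- tracker_config_from(config$track)

  ## background from evenly spaced samples
  idx <- unique(round(seq(1, n_frames,
                          length.out = min(config$background$n_samples,
                                           n_frames))))
  if (length(idx) < 2) idx <- c(1L, max(1L, n_frames))
  bg <- extract_background(lapply(idx, get_frame), idx)

  sil <- config$silhouette
  min_strength <- config$centerline$min_strength
  detections <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    cleaned <- preprocess_frame(get_frame(i), bg,
                                threshold = sil$threshold,
                                open_radius = sil$open_radius,
                                dilate_radius = sil$dilate_radius,
                                max_fraction = sil$max_fraction)
    if (is.null(min_strength)) {
      ## calibrate the ridge threshold once, on the first frame
      derivs <- compute_derivatives(cleaned, config$centerline$sigma)
      min_strength <- calibrate_strength_threshold(
        derivs, config$centerline$threshold_method,
        config$centerline$quantile)
    }
    detections[[i]] <- detect_whiskers(
      cleaned, snout, ccfg, sigma = config$centerline$sigma,
      min_strength = min_strength, fit_cfg = config$fit)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("frame %d/%d: %d whiskers", i, n_frames,
                      nrow(detections[[i]])))
  }

  tracks <- track_whiskers(detections, tcfg)
  out <- list(trace = tracks$trace, tracks = tracks, n_frames = n_frames,
              background = bg, detections = detections, config = config)
  class(out) <- "whisker_run"
  if (!is.null(config$output$dir)) {
    dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
    write_traces(tracks$trace, file.path(config$output$dir, "traces.csv"),
                 fps = fps)
  }
  out
}
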