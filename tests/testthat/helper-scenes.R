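## Small shared fixtures built in code.

test_snout <- function(nr = 200, x = 50) {
  snout_line(c(x, 1), c(x, nr), side_point = c(x + 100, nr / 2))
}

## compact three-whisker scene used across modules
small_scene_config <- function(n_frames = 30, noise_sd = 0.006, fur_n = 25,
                               seed = 11, occlusions = TRUE) {
  snout <- test_snout(200, 50)
  cfg <- scene_config(
    shape = c(200, 280), fps = 1000, n_frames = n_frames, snout = snout,
    whiskers = list(
      whisker_spec(70, 40, deg2rad(104), amplitude = deg2rad(9),
                   length = 110, phase = 0),
      whisker_spec(105, 40, deg2rad(90), amplitude = deg2rad(9),
                   length = 150, phase = 0.4),
      whisker_spec(140, 40, deg2rad(76), amplitude = deg2rad(9),
                   length = 100, phase = 0.8)),
    noise_sd = noise_sd,
    fur = list(n = fur_n, max_len = 12, contrast = 0.18, width = 1.4,
               jitter_sd = 0.4),
    seed = seed)
  cfg
}

scene_background_samples <- function(scene, n = 10) {
  idx <- unique(round(seq(1, scene$cfg$n_frames, length.out = n)))
  extract_background(lapply(idx, function(i) scene_frame(scene, i)), idx)
}

## ordered chain of centerline-like points along a straight line; one point
## per pixel (the detector's invariant), coordinates kept positive
chain_points <- function(n, x0, y0, ang, spacing = 1, drop = integer(0)) {
  s <- (seq_len(n) - 1) * spacing
  df <- data.frame(x = x0 + s * cos(ang), y = y0 + s * sin(ang),
                   direction = rep(ang %% pi, n), strength = 1)
  df$row <- as.integer(round(df$y)); df$col <- as.integer(round(df$x))
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df <- df[!duplicated(df[, c("row", "col")]), , drop = FALSE]
  stopifnot(all(df$row >= 1), all(df$col >= 1))
  rownames(df) <- NULL
  df
}

## cluster from raw xy points (ordered as given)
cluster_from_xy <- function(x, y) {
  whisker_cluster(data.frame(x = x, y = y, direction = NA_real_,
                             strength = 1))
}
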