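test_that("density clustering keeps chains together and splits separated ones", {
  ch <- chain_points(40, 10, 10, deg2rad(30), spacing = 0.9)
  cls <- cluster_dbscan(ch, eps = 2, min_pts = 3)
  expect_length(cls, 1)
  expect_equal(nrow(cls[[1]]$points), nrow(ch))
  ## two parallel chains 10 px apart
  ch2 <- rbind(chain_points(30, 10, 10, 0), chain_points(30, 10, 20, 0))
  cls2 <- cluster_dbscan(ch2, eps = 2, min_pts = 3)
  expect_length(cls2, 2)
  ## sparse uniform scatter: everything is noise
  set.seed(4)
  sparse <- data.frame(x = runif(60, 0, 300), y = runif(60, 0, 300))
  sparse$direction <- 0; sparse$strength <- 1
  sparse$row <- round(sparse$y); sparse$col <- round(sparse$x)
  expect_length(cluster_dbscan(sparse, eps = 2, min_pts = 3), 0)
  expect_true(all(brute_dbscan(sparse$x, sparse$y, 2, 3) == 0))
})

test_that("density clustering agrees with the brute-force reference", {
  set.seed(21)
  for (trial in 1:5) {
    n <- 150
    ## mixture of chains and scatter
    pts <- rbind(
      chain_points(40, runif(1, 5, 20), runif(1, 5, 20), runif(1, 0, pi / 2),
                   spacing = runif(1, 0.8, 1.4)),
      chain_points(40, runif(1, 40, 60), runif(1, 40, 60), runif(1, 0, pi)),
      data.frame(x = runif(n - 80, 0, 90), y = runif(n - 80, 0, 90),
                 direction = 0, strength = 1, row = 0, col = 0))
    eps <- runif(1, 1.5, 3)
    labels_ref <- brute_dbscan(pts$x, pts$y, eps, 3)
    cls <- cluster_dbscan(pts, eps = eps, min_pts = 3)
    got <- integer(nrow(pts))
    for (k in seq_along(cls)) {
      idx <- match(paste(cls[[k]]$points$x, cls[[k]]$points$y),
                   paste(pts$x, pts$y))
      got[idx] <- k
    }
    expect_equal(sum(got == 0), sum(labels_ref == 0))
    keep <- labels_ref != 0
    expect_true(same_partition(got[keep], labels_ref[keep]))
  }
})

test_that("mutual-neighbor clustering follows directions across gaps and crossings", {
  ch <- chain_points(30, 10, 10, deg2rad(40))
  expect_length(cluster_steger(ch, dims = c(60, 60)), 1)
  ## a single missing point (2 px gap) does not break the chain
  ch_gap <- chain_points(30, 10, 10, deg2rad(40), drop = 15)
  expect_length(cluster_steger(ch_gap, dims = c(60, 60)), 1)
  ## X-crossing of two straight chains separated by direction continuity:
  ## linking never mixes directions, and stitching reassembles the chain
  ## interrupted at the junction (only one point exists per shared pixel)
  a <- chain_points(41, 10, 30, deg2rad(20))
  b <- chain_points(41, 10, 50, deg2rad(-25))
  both <- rbind(a, b)
  both <- both[!duplicated(both[, c("row", "col")]), ]
  cls <- cluster_steger(both, dims = c(90, 60))
  for (cl in cls)
    expect_lt(diff(range(cl$points$direction)), deg2rad(10))
  snout <- snout_line(c(8, 1), c(8, 90), side_point = c(50, 45))
  st <- stitch_clusters(cls, cluster_config(), snout)
  expect_length(st, 2)
  dirs <- sort(vapply(st, function(cl)
    median(cl$points$direction), 0))
  expect_equal(dirs, sort(c(deg2rad(20), deg2rad(-25) %% pi)),
               tolerance = 1e-6)
})

test_that("mutual-neighbor clustering agrees with the brute-force graph oracle", {
  set.seed(33)
  for (trial in 1:4) {
    pts <- rbind(
      chain_points(50, runif(1, 5, 15), runif(1, 5, 15),
                   runif(1, 0.1, 1.4)),
      chain_points(50, runif(1, 70, 90), runif(1, 50, 70),
                   runif(1, 1.8, 3.0), drop = c(20, 35)))
    pts <- pts[!duplicated(pts[, c("row", "col")]), ]
    labels_ref <- brute_mutual_components(pts)
    cls <- cluster_steger(pts, dims = c(200, 200))
    got <- integer(nrow(pts))
    for (k in seq_along(cls)) {
      idx <- match(paste(cls[[k]]$points$x, cls[[k]]$points$y),
                   paste(pts$x, pts$y))
      got[idx] <- k
    }
    expect_true(same_partition(got, labels_ref))
  }
})

test_that("stitching merges collinear fragments and respects the gates", {
  snout <- test_snout()
  cfg <- cluster_config()
  ## one whisker broken into two collinear fragments with a 12 px gap
  a <- chain_points(40, 52, 60, deg2rad(10))
  b <- chain_points(40, 52 + 52 * cos(deg2rad(10)), 60 + 52 * sin(deg2rad(10)),
                    deg2rad(10))
  st <- stitch_clusters(list(whisker_cluster(a), whisker_cluster(b)), cfg, snout)
  expect_length(st, 1)
  expect_equal(nrow(st[[1]]$points), nrow(a) + nrow(b))
  ## single cluster unchanged
  st1 <- stitch_clusters(list(whisker_cluster(a)), cfg, snout)
  expect_length(st1, 1)
  expect_equal(nrow(st1[[1]]$points), nrow(a))
  ## laterally offset fragment stays separate; brute-force point-to-line check
  c_off <- chain_points(40, 52 + 52 * cos(deg2rad(10)),
                        60 + 52 * sin(deg2rad(10)) + 8, deg2rad(10))
  st2 <- stitch_clusters(lapply(list(a, b, c_off), whisker_cluster), cfg, snout)
  expect_length(st2, 2)
  tipsec <- a[nrow(a) - 0:19, ]
  dirv <- c(cos(deg2rad(10)), sin(deg2rad(10)))
  perp_b <- abs((b$x[1] - mean(tipsec$x)) * dirv[2] -
                (b$y[1] - mean(tipsec$y)) * dirv[1])
  perp_c <- abs((c_off$x[1] - mean(tipsec$x)) * dirv[2] -
                (c_off$y[1] - mean(tipsec$y)) * dirv[1])
  expect_lt(perp_b, cfg$stitch_max_dist)
  expect_gt(perp_c, cfg$stitch_max_dist)
})

test_that("base-overlap resolution copies the shared segment to the floating cluster", {
  snout <- test_snout()
  cfg <- cluster_config()
  ## shared basal segment from the snout, then two diverging branches
  shared <- chain_points(30, 51, 80, deg2rad(5))
  bx <- shared$x[30] + cos(deg2rad(5)); by <- shared$y[30] + sin(deg2rad(5))
  up <- chain_points(50, bx, by, deg2rad(5))
  down <- chain_points(50, bx + cos(deg2rad(32)), by + sin(deg2rad(32)),
                       deg2rad(32))
  full <- whisker_cluster(rbind(shared, up))       # visible upper whisker
  orphan <- whisker_cluster(down)                  # lower whisker, floating
  out <- resolve_base_overlap(list(full, orphan), snout, cfg)
  d_base <- vapply(out, function(cl)
    abs(snout_dist(snout, cl$base_point)), 0)
  expect_true(all(d_base <= cfg$snout_attach_dist))
  expect_true(any(out[[2]]$points$copied))
  expect_false(any(out[[1]]$points$copied))
  ## identity when everything already reaches the snout
  out2 <- resolve_base_overlap(list(full), snout, cfg)
  expect_equal(nrow(out2[[1]]$points), nrow(full$points))
  ## a floating cluster aligned with nothing is left unchanged
  stray <- whisker_cluster(chain_points(30, 120, 160, deg2rad(100)))
  out3 <- resolve_base_overlap(list(full, stray), snout, cfg)
  expect_false(any(out3[[2]]$points$copied))
})

test_that("fur filtering is by length only", {
  cl_long <- cluster_from_xy(seq(0, 80, by = 1), rep(0, 81))
  cl_short <- cluster_from_xy(seq(0, 8, by = 1), rep(5, 9))
  expect_length(filter_fur(list(cl_long, cl_short), 40), 1)
  expect_length(filter_fur(list(cl_long, cl_short), 0), 2)
  expect_length(filter_fur(list(cl_long), 40), 1)
})

test_that("clustering conserves points (copies excepted and flagged)", {
  sc <- generate_scene(small_scene_config(n_frames = 4))
  bg <- scene_background_samples(sc, 4)
  cleaned <- preprocess_frame(scene_frame(sc, 2), bg)
  dv <- compute_derivatives(cleaned, 1.5)
  pts <- detect_centerline_points(dv)
  for (method in c("dbscan", "steger")) {
    cfg <- cluster_config(method)
    init <- if (method == "dbscan")
      cluster_dbscan(pts, cfg$dbscan_eps, cfg$dbscan_min_pts)
    else cluster_steger(pts, cfg$steger_angle_tol, dims = c(200, 280))
    out <- resolve_base_overlap(stitch_clusters(init, cfg, sc$cfg$snout),
                                sc$cfg$snout, cfg)
    all_pts <- do.call(rbind, lapply(out, `[[`, "points"))
    originals <- all_pts[!all_pts$copied, ]
    key <- paste(originals$x, originals$y)
    expect_false(any(duplicated(key)))                 # no point in 2 clusters
    expect_true(all(key %in% paste(pts$x, pts$y)))     # no invented points
  }
})

test_that("cluster counts match ground truth on clean frames", {
  sc <- generate_scene(small_scene_config(n_frames = 20))
  bg <- scene_background_samples(sc, 8)
  hits <- 0
  for (i in seq(2, 20, by = 2)) {
    cleaned <- preprocess_frame(scene_frame(sc, i), bg)
    dv <- compute_derivatives(cleaned, 1.5)
    pts <- detect_centerline_points(dv)
    cls <- cluster_whiskers(pts, cluster_config(), sc$cfg$snout,
                            dims = c(200, 280))
    hits <- hits + (length(cls) == 3)
  }
  expect_gte(hits, 9)
})
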