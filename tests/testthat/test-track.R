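test_that("optimal assignment matches exhaustive search", {
  set.seed(8)
  for (trial in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:7, 1)
    cost <- matrix(runif(n * m), n, m)
    if (trial %% 3 == 0) cost[sample(n * m, 2)] <- Inf
    got <- solve_assignment(cost)
    ref <- brute_assignment(cost)
    if (n <= m) {
      idx <- cbind(seq_len(n), got)
      expect_equal(sum(cost[idx]), ref$cost, tolerance = 1e-9)
    } else {
      keep <- !is.na(got)
      expect_equal(sum(cost[cbind(which(keep), got[keep])]), ref$cost,
                   tolerance = 1e-9)
    }
  }
  expect_identical(solve_assignment(matrix(numeric(0), 0, 0)), integer(0))
})

test_that("Kalman predict/update follow the closed-form recursion", {
  cfg <- tracker_config()
  st <- kalman_init(list(rho = 100, theta = 1.5, b = 0, L = 150), 1, 1, cfg)
  ## zero velocity: prediction equals the current estimate
  m0 <- kalman_measurement(st)
  m1 <- kalman_measurement(kalman_predict(st))
  expect_equal(m0, m1, tolerance = 1e-12)
  ## covariance trace strictly increases under predict
  expect_gt(sum(diag(kalman_predict(st)$cov)), sum(diag(st$cov)))
  ## independent matrix recursion oracle over 10 noiseless updates of a
  ## constant-velocity angle (theta_dot = 0.01 / frame)
  F <- diag(6); F[1, 3] <- F[2, 4] <- 1
  H <- matrix(0, 4, 6); H[1, 1] <- H[2, 2] <- 1; H[3, 5] <- H[4, 6] <- 1
  Q <- diag(cfg$process_noise^2); R <- diag(cfg$measurement_noise^2)
  x <- c(100, 1.5, 0, 0, 0, 150); P <- st$cov
  st2 <- st
  for (i in 1:10) {
    th_true <- 1.5 + 0.01 * i
    z <- c(100, th_true, 0, 150)
    ## oracle
    x <- drop(F %*% x); P <- F %*% P %*% t(F) + Q
    K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + R)
    x <- x + drop(K %*% (z - drop(H %*% x)))
    P <- (diag(6) - K %*% H) %*% P
    ## implementation
    st2 <- kalman_update(kalman_predict(st2),
                         list(rho = 100, theta = th_true, b = 0, L = 150))
    expect_equal(st2$mean, x, tolerance = 1e-10)
    expect_equal(st2$cov, P, tolerance = 1e-10)
  }
  ## after convergence the filter tracks the moving angle closely
  expect_lt(abs(kalman_measurement(st2)[["theta"]] - 1.6), 0.01)
})

test_that("matching recovers permutations and reports lost/orphans", {
  scales <- c(rho = 5, cot = 0.05, b = 1e-3, L = 5)
  pred <- data.frame(identity = 1:5, rho = c(50, 90, 130, 170, 210),
                     theta = seq(1.8, 1.2, length.out = 5), b = 1e-3,
                     L = seq(120, 200, length.out = 5))
  ## identical detections -> identity assignment at zero cost
  det0 <- pred[, -1]
  m <- match_whiskers(pred, det0, scales, 3)
  expect_equal(m$pairs$identity[order(m$pairs$det)], 1:5)
  expect_lt(max(m$pairs$cost), 1e-9)
  ## noisy permutation -> recovered exactly (oracle: exhaustive assignment)
  set.seed(2)
  perm <- sample(5)
  det <- det0[perm, ]
  det$rho <- det$rho + rnorm(5, 0, 0.5)
  m2 <- match_whiskers(pred, det, scales, 3)
  got <- m2$pairs$identity[order(m2$pairs$det)]
  expect_equal(got, perm)
  cost <- whisktrace:::match_cost_matrix(pred, det, scales)
  expect_equal(sum(cost[cbind(got, seq_len(5))]),
               brute_assignment(cost)$cost, tolerance = 1e-9)
  ## fewer detections than predictions: the rest are lost
  m3 <- match_whiskers(pred, det0[1:3, ], scales, 3)
  expect_setequal(m3$lost, 4:5)
  expect_length(m3$orphans, 0)
})

test_that("bootstrap labels slow whisking correctly and handles edge cases", {
  ## static whiskers: every frame labeled like frame 1
  dets <- make_detection_stream(20, pivots = c(80, 140, 200),
                                rest = c(1.8, 1.5, 1.2), amp = 0)
  res <- bootstrap_tracks(lapply(dets, function(d) d[, -6]),
                          tracker_config(bootstrap_len = 20))
  tr <- res$trace[res$trace$valid, ]
  expect_equal(nrow(tr), 60)
  for (k in 1:3) {
    tk <- tr[tr$identity == k, ]
    expect_lt(diff(range(tk$rho)), 3)
  }
  ## slow sinusoidal whisking at 5 Hz: >= 99% correct identities
  dets2 <- make_detection_stream(80, pivots = c(80, 140, 200),
                                 rest = c(1.8, 1.5, 1.2),
                                 amp = deg2rad(10), freq = 5)
  res2 <- bootstrap_tracks(lapply(dets2, function(d) d[, -6]),
                           tracker_config(bootstrap_len = 80))
  tr2 <- res2$trace[res2$trace$valid, ]
  correct <- 0
  for (i in seq_len(nrow(tr2))) {
    truth_row <- dets2[[tr2$frame[i]]]
    j <- which.min(abs(truth_row$rho - tr2$rho[i]))
    correct <- correct + (truth_row$truth[j] == tr2$identity[i])
  }
  expect_gte(correct / nrow(tr2), 0.99)
  ## bootstrap_len = 1: training window is exactly frame 1
  cfg1 <- tracker_config(bootstrap_len = 1, s = 1000, W = 1000,
                         min_train_samples = 1)
  res3 <- track_whiskers(lapply(dets[1:3], function(d) d[, -6]), cfg1)
  expect_equal(unique(res3$retrains[[1]]$frame), 1)
  expect_length(res3$retrains[[1]]$uids, 3)
})

test_that("identities are exclusive and capped at the frame-1 count", {
  dets <- make_detection_stream(60, pivots = c(80, 140, 200),
                                rest = c(1.8, 1.5, 1.2), amp = deg2rad(8))
  ## inject a duplicate detection every 10th frame
  dets <- lapply(seq_along(dets), function(i) {
    d <- dets[[i]][, -6]
    if (i %% 10 == 0) d <- rbind(d, d[2, ] + c(0.3, 0.001, 0, 0.2))
    d
  })
  res <- track_whiskers(dets, tracker_config(bootstrap_len = 20, s = 10,
                                             min_train_samples = 10))
  tr <- res$trace[res$trace$valid, ]
  expect_equal(res$n_identities, 3)
  per_frame <- table(tr$frame)
  expect_true(all(per_frame <= 3))
  expect_false(any(duplicated(tr[, c("frame", "identity")])))
})

test_that("the P-expert restores an occluded identity at reappearance", {
  drop <- data.frame(frame = rep(40:59, each = 1), whisker = 2)
  dets <- make_detection_stream(90, pivots = c(80, 140, 200),
                                rest = c(1.8, 1.5, 1.2), amp = deg2rad(8),
                                drop = drop)
  res <- track_whiskers(lapply(dets, function(d) d[, -6]),
                        tracker_config(bootstrap_len = 20, s = 10,
                                       min_train_samples = 10))
  tr <- res$trace[res$trace$valid, ]
  ## identity 2 (middle whisker) disappears exactly over the occlusion and
  ## comes back with the same label
  f2 <- sort(tr$frame[tr$identity == 2])
  expect_false(any(40:59 %in% f2))
  expect_true(60 %in% f2 || 61 %in% f2)
  post <- tr[tr$identity == 2 & tr$frame > 59, ]
  truth_rho <- vapply(post$frame, function(f)
    dets[[f]]$rho[dets[[f]]$truth == 2], 0)
  expect_lt(max(abs(post$rho - truth_rho)), 2)
  ## no orphans, no recoveries case
  m <- match_whiskers(data.frame(identity = integer(), rho = numeric(),
                                 theta = numeric(), b = numeric(),
                                 L = numeric()),
                      dets[[1]][, -6], c(rho = 5, cot = 0.05, b = 1e-3, L = 5))
  expect_equal(nrow(m$pairs), 0)
})
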