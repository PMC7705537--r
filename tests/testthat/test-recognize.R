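test_that("feature vectors use cot(theta) and previous-frame offsets", {
  d <- data.frame(rho = c(100, 150), theta = c(pi / 2, 1.2), b = 1e-3,
                  L = c(120, 150))
  f <- build_features(d, prev_means = c(rho = 110, cot = 0.1))
  expect_equal(f$cot[1], 0)
  expect_equal(f$cot[2], 1 / tan(1.2))
  expect_equal(f$d_rho, c(-10, 40))
  expect_equal(f$d_cot, f$cot - 0.1)
  ## params equal to previous means give zero offsets
  f2 <- build_features(data.frame(rho = 110, theta = pi / 2, b = 0, L = 1),
                       prev_means = c(rho = 110, cot = 0))
  expect_equal(f2$d_rho, 0); expect_equal(f2$d_cot, 0)
})

make_window <- function(N, per_class = 30, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(N), function(k) {
      data.frame(frame = seq_len(per_class), identity = k,
                 L = 150 + sep * k + rnorm(per_class),
                 b = 1e-3 + rnorm(per_class, 0, 1e-4),
                 rho = 50 + 30 * k + rnorm(per_class),
                 cot = 0.1 * k + rnorm(per_class, 0, 0.02),
                 d_rho = rnorm(per_class), d_cot = rnorm(per_class, 0, 0.02),
                 uid = k * 1000 + seq_len(per_class))
    }))
  })
}

test_that("the ensemble has one classifier per identity pair and standardizes features", {
  cfg <- tracker_config(min_train_samples = 10)
  ens5 <- train_classifier(make_window(5), cfg)
  expect_equal(ens5$n_classifiers, 10)          # 5 * 4 / 2
  expect_equal(length(ens5$classes), 5)
  ## standardization over the window: mean 0, sd 1 per feature
  w <- make_window(5)
  X <- as.matrix(w[, whisktrace:::feature_cols])
  Xs <- sweep(sweep(X, 2, ens5$mu), 2, ens5$sig, "/")
  expect_lt(max(abs(colMeans(Xs))), 1e-9)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-9)
  ## single identity: no classifiers
  expect_null(train_classifier(make_window(1), cfg))
  ## identity with too few samples is excluded from voting
  w2 <- rbind(make_window(3), make_window(4)[91:95, ])
  ens2 <- train_classifier(w2, cfg)
  expect_equal(ens2$n_classifiers, 3)
  expect_equal(ens2$excluded, 4L)
})

test_that("classification is perfect on separable classes and N=2 reduces to one SVM", {
  cfg <- tracker_config(min_train_samples = 10)
  w <- make_window(4, sep = 8)
  ens <- train_classifier(w, cfg)
  cls <- classify_whiskers(ens, w)
  expect_equal(cls$identity, w$identity)        # 100% training accuracy
  expect_true(all(cls$margin >= 1))
  ## N=2: decision equals the sign of the single pairwise decision value
  w2 <- make_window(2)
  ens2 <- train_classifier(w2, cfg)
  expect_equal(ens2$n_classifiers, 1)
  X <- as.matrix(w2[, whisktrace:::feature_cols])
  Xs <- sweep(sweep(X, 2, ens2$mu), 2, ens2$sig, "/")
  dv <- drop(Xs %*% ens2$W[1, ]) - ens2$b[1]
  pred <- ifelse(dv > 0, ens2$pos[1], ens2$neg[1])
  expect_equal(classify_whiskers(ens2, w2)$identity, pred)
})

test_that("accuracy on overlapping classes approaches the Bayes rate", {
  ## two identities overlapping in every feature; Bayes rate from the
  ## generating densities by Monte Carlo
  cfg <- tracker_config(min_train_samples = 10)
  mu1 <- c(L = 150, b = 1e-3, rho = 100, cot = 0.0, d_rho = 0, d_cot = 0)
  mu2 <- c(L = 153, b = 1e-3, rho = 103, cot = 0.05, d_rho = 0, d_cot = 0)
  sds <- c(L = 2, b = 1e-4, rho = 2, cot = 0.04, d_rho = 1, d_cot = 0.03)
  gen <- function(mu, n, seed) withr::with_seed(seed, {
    as.data.frame(t(replicate(n, rnorm(6, mu, sds))))
  })
  tr1 <- gen(mu1, 150, 41); tr2 <- gen(mu2, 150, 42)
  names(tr1) <- names(tr2) <- names(mu1)
  w <- rbind(cbind(frame = 1, identity = 1, tr1, uid = 1:150),
             cbind(frame = 1, identity = 2, tr2, uid = 151:300))
  ens <- train_classifier(w, cfg)
  te1 <- gen(mu1, 500, 43); te2 <- gen(mu2, 500, 44)
  names(te1) <- names(te2) <- names(mu1)
  acc <- mean(c(classify_whiskers(ens, te1)$identity == 1,
                classify_whiskers(ens, te2)$identity == 2))
  ## Monte-Carlo Bayes rate: likelihood-ratio rule under the true densities
  loglik <- function(x, mu) sum(dnorm(as.numeric(x), mu, sds, log = TRUE))
  bayes <- mean(c(apply(te1, 1, function(x) loglik(x, mu1) >= loglik(x, mu2)),
                  apply(te2, 1, function(x) loglik(x, mu2) > loglik(x, mu1))))
  expect_gt(acc, bayes - 0.05)
})

test_that("the N-expert flags implausible jumps with a strict threshold", {
  prev <- list(rho = 100, theta = deg2rad(90))
  thr <- deg2rad(10)
  ## 12-degree jump in one frame is physically impossible -> false positive
  expect_false(n_expert(list(rho = 100, theta = deg2rad(102)), prev,
                        max_dtheta = thr)$valid)
  expect_identical(n_expert(list(rho = 100, theta = deg2rad(102)), prev,
                            max_dtheta = thr)$reason, "theta_jump")
  ## no change is valid; exactly at threshold is valid (strict inequality)
  expect_true(n_expert(prev, prev, max_dtheta = thr)$valid)
  expect_true(n_expert(list(rho = 100, theta = deg2rad(100)), prev,
                       max_dtheta = thr)$valid)
  expect_true(n_expert(list(rho = 115, theta = deg2rad(90)), prev,
                       max_drho = 15)$valid)
  expect_false(n_expert(list(rho = 115.1, theta = deg2rad(90)), prev,
                        max_drho = 15)$valid)
})

test_that("pivot estimation recovers (L_f, rho_f) and flags degeneracy", {
  th <- seq(deg2rad(60), deg2rad(120), length.out = 100)
  rho <- 40 / tan(th) + 120
  est <- estimate_pivot(rho, th)
  expect_equal(est$L_f, 40, tolerance = 1e-9)
  expect_equal(est$rho_f, 120, tolerance = 1e-9)
  expect_false(est$degenerate)
  expect_gt(est$r2, 1 - 1e-12)
  ## noisy: within 3 OLS standard errors in nearly all trials
  set.seed(12)
  hits <- 0
  for (i in 1:200) {
    rho_n <- rho + rnorm(100, 0, 0.5)
    e <- estimate_pivot(rho_n, th)
    hits <- hits + (abs(e$L_f - 40) <= 3 * e$se_Lf &&
                    abs(e$rho_f - 120) <= 3 * e$se_rhof)
  }
  expect_gte(hits / 200, 0.97)
  ## all theta equal: slope unidentifiable
  e0 <- estimate_pivot(rep(c(119, 121), 30), rep(pi / 2, 60),
                       min_theta_range = deg2rad(10))
  expect_true(e0$degenerate)
  expect_equal(e0$rho_f, 120)
  expect_true(is.na(e0$L_f))
  expect_error(estimate_pivot(rho[1:10], th[1:10]), "samples")
})

test_that("flagged false positives never re-enter training windows", {
  ## inject theta jumps into an otherwise clean detection stream
  n_frames <- 120
  dets <- make_detection_stream(n_frames, pivots = c(70, 130, 190, 250),
                                rest = c(1.9, 1.65, 1.4, 1.15),
                                amp = deg2rad(8))
  inject_frames <- seq(45, 115, by = 5)
  for (f in inject_frames)
    dets[[f]]$theta[2] <- dets[[f]]$theta[2] + deg2rad(14)
  dets <- lapply(seq_along(dets), function(i) {
    d <- dets[[i]][, c("rho", "theta", "b", "L")]
    d$uid <- i * 1000 + seq_len(nrow(d))
    d
  })
  res <- track_whiskers(dets, tracker_config(bootstrap_len = 20, s = 10,
                                             min_train_samples = 10))
  fl <- res$flagged
  expect_gte(sum(fl$frame %in% inject_frames & fl$reason == "theta_jump"),
             0.95 * length(inject_frames))
  ## hygiene: no flagged uid in any later training window, or in the output
  for (i in seq_len(nrow(fl))) {
    later <- Filter(function(r) r$frame >= fl$frame[i], res$retrains)
    for (r in later) expect_false(fl$uid[i] %in% r$uids)
  }
  valid <- res$trace[res$trace$valid, ]
  inj_uids <- vapply(inject_frames, function(f) dets[[f]]$uid[2], 0)
  flagged_inj <- intersect(inj_uids, fl$uid)
  ## flagged injected detections are absent from the accepted output rows of
  ## their own identity at the injected frame
  for (f in inject_frames) {
    row <- valid[valid$frame == f & valid$identity == 2, ]
    if (nrow(row)) expect_lt(abs(row$theta -
      (dets[[f]]$theta[2] - deg2rad(14))), deg2rad(14))
  }
  expect_gte(length(flagged_inj), 0.95 * length(inj_uids))
})
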