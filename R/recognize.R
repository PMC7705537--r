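#' Build the recognition feature vector
#'
#' Per detection: length `L`, bending `b`, base position `rho`, `cot(theta)`,
#' and the offsets of `rho` and `cot(theta)` from the previous frame's means
#' over all accepted whiskers (the previous frame is used because the current
#' frame's means are only known once every whisker is identified).
#' `cot(theta)` is used instead of `theta` because it is linear in `rho`
#' under the fixed-pivot geometry, which makes whiskers nearly linearly
#' separable in feature space.
#'
#' @param dets data frame of detections with columns `rho`, `theta`, `b`, `L`
#' @param prev_means numeric: `c(rho = , cot = )`, the previous frame's means
#'   (a frame with no predecessor uses its own means)
#' @return `dets` with added columns `cot`, `d_rho`, `d_cot`
#' @export
build_features <- function(dets, prev_means = NULL) {
  dets$cot <- cos(dets$theta) / sin(dets$theta)
  if (is.null(prev_means))
    prev_means <- c(rho = mean(dets$rho), cot = mean(dets$cot))
  dets$d_rho <- dets$rho - prev_means[["rho"]]
  dets$d_cot <- dets$cot - prev_means[["cot"]]
  dets
}

feature_cols <- c("L", "b", "rho", "cot", "d_rho", "d_cot")

#' Train the one-vs-one recognizer ensemble
#'
#' One linear soft-margin support-vector machine per identity pair, trained
#' on the standardized feature vectors of the sliding training window —
#' exactly `N * (N - 1) / 2` classifiers when all `N` identities have enough
#' samples. Identities with fewer than `min_train_samples` examples are
#' excluded from voting for this cycle.
#'
#' @param window data frame of labeled features: columns [feature_cols] plus
#'   `identity` (and optionally `frame`, `uid`)
#' @param cfg a [tracker_config]
#' @return object of class `whisker_ensemble` (or `NULL` when fewer than two
#'   identities are trainable): weight matrix evaluation of the pairwise
#'   decision functions, standardization statistics, class centroids
#' @export
train_classifier <- function(window, cfg) {
  counts <- table(window$identity)
  classes <- as.integer(names(counts)[counts >= cfg$min_train_samples])
  excluded <- as.integer(names(counts)[counts < cfg$min_train_samples])
  if (length(classes) < 2) return(NULL)
  ## cap samples per class at the most recent max_train_per_class
  keep <- unlist(lapply(classes, function(k) {
    idx <- which(window$identity == k)
    tail(idx, cfg$max_train_per_class)
  }))
  w <- window[sort(keep), , drop = FALSE]
  X <- as.matrix(w[, feature_cols])
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  sig[sig < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sig, "/")
  y <- w$identity
  pairs <- combn(classes, 2)
  Wm <- matrix(0, ncol(pairs), length(feature_cols))
  b <- numeric(ncol(pairs))
  pos <- integer(ncol(pairs)); neg <- integer(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sel <- y == i | y == j
    yy <- factor(y[sel], levels = c(i, j))
    fit <- e1071::svm(Xs[sel, , drop = FALSE], yy, kernel = "linear",
                      cost = cfg$svm_cost, scale = FALSE)
    wv <- drop(crossprod(fit$coefs, fit$SV))
    ## orient the raw decision value: positive -> class i
    dv <- drop(Xs[sel, , drop = FALSE] %*% wv) - fit$rho
    pr <- predict(fit, Xs[sel, , drop = FALSE])
    agree <- mean((dv > 0) == (pr == as.character(i)))
    if (agree < 0.5) { wv <- -wv; fit$rho <- -fit$rho }
    Wm[p, ] <- wv
    b[p] <- fit$rho
    pos[p] <- i; neg[p] <- j
  }
  cent <- t(vapply(classes, function(k)
    colMeans(Xs[y == k, , drop = FALSE]), numeric(length(feature_cols))))
  rownames(cent) <- classes
  structure(list(classes = classes, excluded = excluded, W = Wm, b = b,
                 pos = pos, neg = neg, mu = mu, sig = sig,
                 centroids = cent, n_classifiers = ncol(pairs)),
            class = "whisker_ensemble")
}

#' Classify detections with the one-vs-one ensemble
#'
#' Majority vote over the pairwise classifiers; the margin is the vote count
#' of the winner minus the runner-up. Vote ties are resolved by the smaller
#' standardized distance to the class centroid.
#'
#' @param ensemble a `whisker_ensemble` from [train_classifier()], or `NULL`
#' @param feats data frame of features (columns [feature_cols]); one row per
#'   detection
#' @return data frame with `identity` and `margin` per detection (`NA`
#'   identity when no ensemble is available)
#' @export
classify_whiskers <- function(ensemble, feats) {
  n <- nrow(feats)
  if (is.null(ensemble) || n == 0)
    return(data.frame(identity = rep(NA_integer_, n),
                      margin = rep(NA_real_, n)))
  X <- as.matrix(feats[, feature_cols, drop = FALSE])
  Xs <- sweep(sweep(X, 2, ensemble$mu), 2, ensemble$sig, "/")
  dv <- Xs %*% t(ensemble$W) - rep(ensemble$b, each = n)
  ids <- integer(n); marg <- numeric(n)
  for (i in seq_len(n)) {
    votes <- ifelse(dv[i, ] > 0, ensemble$pos, ensemble$neg)
    tab <- table(factor(votes, levels = ensemble$classes))
    top <- max(tab)
    winners <- as.integer(names(tab)[tab == top])
    if (length(winners) > 1) {
      d2 <- vapply(winners, function(k)
        sum((Xs[i, ] - ensemble$centroids[as.character(k), ])^2), 0)
      winners <- winners[order(d2, winners)]
    }
    ids[i] <- winners[1]
    marg[i] <- top - if (length(tab) > 1) max(tab[names(tab) !=
                                                   as.character(winners[1])]) else 0
  }
  data.frame(identity = ids, margin = marg)
}

#' N-expert plausibility check
#'
#' A whisker cannot move arbitrarily fast: if the base position or angle of a
#' candidate detection differs from the identity's accepted parameters in the
#' immediately preceding frame by more than the per-frame thresholds, the
#' detection is marked a false positive and must be removed from both the
#' output and the training data. The comparison is strict (`>`); a change
#' exactly at the threshold passes.
#'
#' @param candidate list/row with `rho`, `theta`
#' @param prev the identity's accepted parameters in the previous frame
#' @param max_dtheta threshold on `|delta theta|` (radians/frame)
#' @param max_drho threshold on `|delta rho|` (px/frame)
#' @return list with `valid` (logical) and `reason` (`NA` or
#'   `"theta_jump"` / `"rho_jump"`)
#' @export
n_expert <- function(candidate, prev, max_dtheta = deg2rad(10),
                     max_drho = 15) {
  tol <- 1e-9   # a change exactly at the threshold passes
  dth <- abs(candidate$theta - prev$theta)
  drh <- abs(candidate$rho - prev$rho)
  if (dth > max_dtheta + tol) return(list(valid = FALSE, reason = "theta_jump"))
  if (drh > max_drho + tol) return(list(valid = FALSE, reason = "rho_jump"))
  list(valid = TRUE, reason = NA_character_)
}

#' Estimate a whisker's hidden pivot point
#'
#' Under rotation about a fixed pivot behind the snout line, base position
#' and angle are linked by `rho = L_f * cot(theta) + rho_f`, with `L_f` the
#' pivot depth behind the line and `rho_f` the foot of its perpendicular.
#' Ordinary least squares of `rho` on `cot(theta)` recovers both constants.
#'
#' @param rho,theta numeric vectors of matched observations for one identity
#' @param min_samples minimum number of samples
#' @param min_theta_range minimum spread of `theta` (radians); with no
#'   angular spread the slope is unidentifiable
#' @return object of class `pivot_estimate`: `rho_f`, `L_f`, `r2`, standard
#'   errors, `degenerate` flag (`L_f = NA`, `rho_f = mean(rho)` when
#'   degenerate)
#' @export
estimate_pivot <- function(rho, theta, min_samples = 50,
                           min_theta_range = deg2rad(10)) {
  ok <- is.finite(rho) & is.finite(theta)
  rho <- rho[ok]; theta <- theta[ok]
  if (length(rho) < min_samples)
    stop(sprintf("pivot estimation needs >= %d samples", min_samples))
  ct <- cos(theta) / sin(theta)
  if (diff(range(theta)) < min_theta_range || sd(ct) < 1e-9) {
    return(structure(list(rho_f = mean(rho), L_f = NA_real_, r2 = NA_real_,
                          se_Lf = NA_real_, se_rhof = NA_real_,
                          degenerate = TRUE),
                     class = "pivot_estimate"))
  }
  fit <- lm(rho ~ ct)
  sm <- summary(fit)
  structure(list(rho_f = unname(coef(fit)[1]), L_f = unname(coef(fit)[2]),
                 r2 = sm$r.squared,
                 se_rhof = sm$coefficients[1, 2],
                 se_Lf = sm$coefficients[2, 2],
                 degenerate = FALSE),
            class = "pivot_estimate")
}
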