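#' Tracker configuration
#'
#' @param bootstrap_len length of the bootstrap period (frames) during which
#'   identities are followed by the Kalman tracker alone to seed the
#'   recognizer's training set; works best while whisking is slow
#' @param s retrain cadence of the recognizer (frames)
#' @param W training window (frames): each retrain uses the accepted,
#'   labeled detections of frames `n - W` to `n`
#' @param max_train_per_class cap on (most recent) training samples per
#'   identity per retrain
#' @param min_train_samples identities with fewer window samples are excluded
#'   from voting for the cycle
#' @param assign_max_cost gate on the normalized parameter distance of an
#'   assignment pair (dimensionless)
#' @param max_dtheta,max_drho N-expert per-frame jump thresholds (radians
#'   and px per frame)
#' @param max_coast lost tracks keep predicting for this many frames, then
#'   freeze
#' @param max_lost_bootstrap warn when an identity is lost for more than this
#'   many consecutive bootstrap frames (degraded training set)
#' @param svm_cost soft-margin cost of the linear SVMs
#' @param process_noise,measurement_noise Kalman noise standard deviations
#'   over (`rho`, `theta`, `rho_dot`, `theta_dot`, `b`, `L`) and (`rho`,
#'   `theta`, `b`, `L`)
#' @param init_velocity_var initial velocity variance
#' @param scale_floor named floors for the running parameter scales used in
#'   assignment costs
#' @return a `tracker_config` list
#' @export
tracker_config <- function(bootstrap_len = 50, s = 25, W = 2000,
                           max_train_per_class = 200, min_train_samples = 20,
                           assign_max_cost = 3,
                           max_dtheta = deg2rad(10), max_drho = 15,
                           max_coast = 100, max_lost_bootstrap = 10,
                           svm_cost = 1,
                           process_noise = c(0.3, 0.003, 0.3, 0.003,
                                             2e-4, 1),
                           measurement_noise = c(0.7, 0.008, 3e-4, 1.5),
                           init_velocity_var = 1,
                           scale_floor = c(rho = 5, cot = 0.05, b = 1e-3,
                                           L = 5)) {
  stopifnot(bootstrap_len >= 1, s >= 1, W >= 1, assign_max_cost > 0,
            max_dtheta > 0, max_drho > 0, max_coast >= 0)
  structure(as.list(environment()), class = "tracker_config")
}

## running scales of the assignment features, floored for stability
param_scales <- function(df, cfg) {
  ct <- if (!is.null(df$cot)) df$cot else cos(df$theta) / sin(df$theta)
  s <- c(rho = sd(df$rho), cot = sd(ct), b = sd(df$b), L = sd(df$L))
  s[!is.finite(s)] <- 0
  pmax(s, cfg$scale_floor)
}

## normalized parameter distance matrix between two parameter tables
match_cost_matrix <- function(pred, dets, scales) {
  pc <- cos(pred$theta) / sin(pred$theta)
  dc <- cos(dets$theta) / sin(dets$theta)
  z <- function(a, b, s) outer(a, b, "-")^2 / s^2
  sqrt((z(pred$rho, dets$rho, scales["rho"]) + z(pc, dc, scales["cot"]) +
        z(pred$b, dets$b, scales["b"]) + z(pred$L, dets$L, scales["L"])) / 4)
}

#' Match predicted whiskers to detections
#'
#' Minimum-total-cost one-to-one assignment on the normalized parameter
#' distance (over `rho`, `cot(theta)`, `b`, `L`, each scaled by its running
#' standard deviation); pairs costlier than `max_cost` are rejected.
#'
#' @param pred data frame of predictions with columns `identity`, `rho`,
#'   `theta`, `b`, `L`
#' @param dets data frame of detections (`rho`, `theta`, `b`, `L`)
#' @param scales named numeric scales (`rho`, `cot`, `b`, `L`)
#' @param max_cost assignment gate
#' @param forbid optional 2-column matrix of (identity, detection index)
#'   pairs that must not be matched
#' @return list: `pairs` (data frame `identity`, `det`, `cost`), `lost`
#'   (unmatched identities), `orphans` (unmatched detection indices)
#' @export
match_whiskers <- function(pred, dets, scales, max_cost = 3, forbid = NULL) {
  if (nrow(pred) == 0 || nrow(dets) == 0)
    return(list(pairs = data.frame(identity = integer(), det = integer(),
                                   cost = numeric()),
                lost = pred$identity, orphans = seq_len(nrow(dets))))
  cost <- match_cost_matrix(pred, dets, scales)
  if (!is.null(forbid) && nrow(forbid) > 0)
    for (k in seq_len(nrow(forbid))) {
      i <- match(forbid[k, 1], pred$identity)
      if (!is.na(i)) cost[i, forbid[k, 2]] <- Inf
    }
  assn <- solve_assignment(cost)
  keep <- which(!is.na(assn))
  keep <- keep[cost[cbind(keep, assn[keep])] <= max_cost]
  pairs <- data.frame(identity = pred$identity[keep], det = assn[keep],
                      cost = cost[cbind(keep, assn[keep])])
  list(pairs = pairs,
       lost = pred$identity[setdiff(seq_len(nrow(pred)), keep)],
       orphans = setdiff(seq_len(nrow(dets)), assn[keep]))
}

## ---------------------------------------------------------------------------
## full tracking-learning-detection driver
## ---------------------------------------------------------------------------

#' Track whisker identities across frames
#'
#' Follows the whiskers visible on the first frame through the whole
#' recording. A bootstrap period uses Kalman prediction plus optimal
#' assignment alone and seeds the recognizer's training window. Afterwards,
#' each frame is processed in the order: one-vs-one SVM classification,
#' N-expert plausibility check (implausible per-frame jumps are flagged false
#' positive and barred from output and training), then the Kalman tracker
#' acting as P-expert matches still-orphaned detections to lost tracks
#' (recovered matches re-enter output and training). An identity undetected
#' by both keeps its Kalman estimate, flagged `estimated` and excluded from
#' the valid output. The recognizer is retrained every `s` frames on the
#' sliding window.
#'
#' @param detections list (one element per frame) of data frames with
#'   columns `rho`, `theta`, `b`, `L` (optionally `rss`, `uid`; a unique
#'   `uid` is assigned when missing)
#' @param cfg a [tracker_config]
#' @return object of class `whisker_tracks`: `trace` (a trace table: `frame`,
#'   `identity`, `rho`, `theta`, `b`, `L`, `rss`, `status`, `valid`),
#'   `events`, `flagged` (N-expert verdicts), `retrains` (per retrain: frame
#'   and training-sample uids), `n_identities`
#' @export
track_whiskers <- function(detections, cfg = tracker_config()) {
  n_frames <- length(detections)
  for (i in seq_len(n_frames)) {
    d <- detections[[i]]
    if (is.null(d$uid) && nrow(d) > 0)
      detections[[i]]$uid <- i * 10000 + seq_len(nrow(d))
    if (is.null(d$rss)) detections[[i]]$rss <- NA_real_
  }
  empty_trace <- data.frame(frame = integer(), identity = integer(),
                            rho = numeric(), theta = numeric(),
                            b = numeric(), L = numeric(), rss = numeric(),
                            status = character(), valid = logical())
  d0 <- detections[[1]]
  if (is.null(d0) || nrow(d0) == 0)
    return(structure(list(trace = empty_trace,
                          events = data.frame(), flagged = data.frame(),
                          retrains = list(), n_identities = 0L, cfg = cfg),
                     class = "whisker_tracks"))
  ## identities fixed at frame 1, numbered by base position
  d0 <- d0[order(d0$rho), , drop = FALSE]
  N <- nrow(d0)
  states <- vector("list", N)
  prev_acc <- vector("list", N)   # last accepted row (list with frame/params)
  for (k in seq_len(N))
    states[[k]] <- kalman_init(as.list(d0[k, ]), k, 1L, cfg)

  ## preallocated numeric accumulators (1-row data frames do not scale)
  status_levels <- c("tracked", "recognized", "recovered", "estimated")
  tr_mat <- matrix(NA_real_, n_frames * N, 8)
  colnames(tr_mat) <- c("frame", "identity", "rho", "theta", "b", "L",
                        "rss", "status_code")
  tr_valid <- logical(n_frames * N)
  tr_n <- 0L
  tm <- matrix(NA_real_, n_frames * N, 9)
  colnames(tm) <- c("frame", "identity", feature_cols, "uid")
  tm_n <- 0L
  events <- list()
  flagged <- list()
  retrains <- list()
  lost_streak <- integer(N)

  add_trace <- function(frame, identity, p, status, valid) {
    tr_n <<- tr_n + 1L
    tr_mat[tr_n, ] <<- c(frame, identity, p$rho, p$theta, p$b, p$L,
                         if (is.null(p$rss) || length(p$rss) == 0)
                           NA_real_ else p$rss,
                         match(status, status_levels))
    tr_valid[tr_n] <<- valid
  }
  add_training <- function(frame, identity, feat_row) {
    tm_n <<- tm_n + 1L
    tm[tm_n, ] <<- c(frame, identity,
                     as.numeric(feat_row[1, feature_cols]), feat_row$uid[1])
  }

  ## frame 1: all detections accepted as their identities
  f1 <- build_features(d0)
  for (k in seq_len(N)) {
    add_trace(1L, k, as.list(d0[k, ]), "tracked", TRUE)
    add_training(1L, k, f1[k, , drop = FALSE])
    prev_acc[[k]] <- list(frame = 1L, rho = d0$rho[k], theta = d0$theta[k])
  }
  prev_means <- c(rho = mean(d0$rho), cot = mean(f1$cot))
  scales <- param_scales(d0, cfg)
  ensemble <- NULL

  training_window <- function(n) {
    w <- tm[seq_len(tm_n), , drop = FALSE]
    as.data.frame(w[w[, "frame"] >= n - cfg$W, , drop = FALSE])
  }
  do_retrain <- function(n) {
    win <- training_window(n)
    ens <- train_classifier(win, cfg)
    retrains[[length(retrains) + 1]] <<- list(frame = n, uids = win$uid)
    if (nrow(win) > 4) scales <<- param_scales(win, cfg)
    if (!is.null(ens))
      events[[length(events) + 1]] <<-
        data.frame(frame = n, identity = NA_integer_, event = "retrain",
                   uid = NA_real_)
    ens
  }

  accept <- function(n, k, det_row, status) {
    ## Kalman: re-init after long gaps, otherwise update
    gap <- n - states[[k]]$last_seen
    if (gap > 3) states[[k]] <<- kalman_init(as.list(det_row), k, n, cfg)
    else states[[k]] <<- kalman_update(states[[k]], as.list(det_row), n)
    prev_acc[[k]] <<- list(frame = n, rho = det_row$rho,
                           theta = det_row$theta)
  }

  if (cfg$bootstrap_len <= 1)
    ensemble <- do_retrain(1)

  for (n in seq_len(n_frames)[-1]) {
    dets <- detections[[n]]
    for (k in seq_len(N)) {
      if (n - states[[k]]$last_seen <= cfg$max_coast)
        states[[k]] <- kalman_predict(states[[k]])
    }
    accepted <- list()    # per identity: det row
    used_dets <- integer(0)
    in_bootstrap <- n <= cfg$bootstrap_len
    feats <- if (nrow(dets) > 0) build_features(dets, prev_means) else dets

    if (!in_bootstrap && !is.null(ensemble) && nrow(dets) > 0) {
      cls <- classify_whiskers(ensemble, feats)
      ## resolve identity conflicts by margin (ties: lowest det index)
      for (k in unique(na.omit(cls$identity))) {
        cand <- which(cls$identity == k)
        cand <- cand[order(-cls$margin[cand], cand)]
        sel <- cand[1]
        verdict <- list(valid = TRUE, reason = NA_character_)
        if (!is.null(prev_acc[[k]]) && prev_acc[[k]]$frame == n - 1L)
          verdict <- n_expert(as.list(dets[sel, ]), prev_acc[[k]],
                              cfg$max_dtheta, cfg$max_drho)
        if (verdict$valid) {
          accepted[[as.character(k)]] <-
            cbind(dets[sel, , drop = FALSE], status = "recognized")
          used_dets <- c(used_dets, sel)
        } else {
          flagged[[length(flagged) + 1]] <-
            data.frame(frame = n, identity = k, uid = dets$uid[sel],
                       reason = verdict$reason)
          events[[length(events) + 1]] <-
            data.frame(frame = n, identity = k, event = "false_positive",
                       uid = dets$uid[sel])
        }
      }
    }

    ## tracker pass: bootstrap matching, or P-expert for the remainder
    remaining_ids <- setdiff(seq_len(N), as.integer(names(accepted)))
    remaining_ids <- remaining_ids[
      vapply(remaining_ids, function(k)
        n - states[[k]]$last_seen <= cfg$max_coast, TRUE)]
    orphans <- setdiff(seq_len(nrow(dets)), used_dets)
    if (length(remaining_ids) > 0 && length(orphans) > 0) {
      pred <- do.call(rbind, lapply(remaining_ids, function(k) {
        m <- kalman_measurement(states[[k]])
        data.frame(identity = k, rho = m["rho"], theta = m["theta"],
                   b = m["b"], L = m["L"])
      }))
      ## flagged (identity, det) pairs of this frame are barred
      forbid <- if (length(flagged)) {
        fl <- do.call(rbind, flagged)
        fl <- fl[fl$frame == n, c("identity", "uid"), drop = FALSE]
        if (nrow(fl)) cbind(fl$identity, match(fl$uid, dets$uid)) else NULL
      } else NULL
      mres <- match_whiskers(pred, dets[orphans, , drop = FALSE], scales,
                             cfg$assign_max_cost, forbid = {
                               if (!is.null(forbid)) {
                                 fb <- forbid
                                 fb[, 2] <- match(fb[, 2], orphans)
                                 fb[!is.na(fb[, 2]), , drop = FALSE]
                               } else NULL
                             })
      if (nrow(mres$pairs) > 0) for (r in seq_len(nrow(mres$pairs))) {
        k <- mres$pairs$identity[r]
        sel <- orphans[mres$pairs$det[r]]
        verdict <- list(valid = TRUE, reason = NA_character_)
        if (!is.null(prev_acc[[k]]) && prev_acc[[k]]$frame == n - 1L)
          verdict <- n_expert(as.list(dets[sel, ]), prev_acc[[k]],
                              cfg$max_dtheta, cfg$max_drho)
        if (verdict$valid) {
          st <- if (in_bootstrap) "tracked"
                else if (n - states[[k]]$last_seen > 1) "recovered"
                else "tracked"
          accepted[[as.character(k)]] <-
            cbind(dets[sel, , drop = FALSE], status = st)
          used_dets <- c(used_dets, sel)
        } else {
          flagged[[length(flagged) + 1]] <-
            data.frame(frame = n, identity = k, uid = dets$uid[sel],
                       reason = verdict$reason)
          events[[length(events) + 1]] <-
            data.frame(frame = n, identity = k, event = "false_positive",
                       uid = dets$uid[sel])
        }
      }
    }

    ## commit accepted detections, estimate the rest
    for (k in seq_len(N)) {
      key <- as.character(k)
      if (!is.null(accepted[[key]])) {
        det_row <- accepted[[key]]
        accept(n, k, det_row, det_row$status)
        add_trace(n, k, as.list(det_row), det_row$status, TRUE)
        fi <- match(det_row$uid, feats$uid)
        add_training(n, k, feats[fi, , drop = FALSE])
        if (det_row$status == "recovered")
          events[[length(events) + 1]] <-
            data.frame(frame = n, identity = k, event = "recovered",
                       uid = det_row$uid)
        lost_streak[k] <- 0L
      } else {
        states[[k]]$status <- "estimated"
        m <- kalman_measurement(states[[k]])
        add_trace(n, k, as.list(m), "estimated", FALSE)
        lost_streak[k] <- lost_streak[k] + 1L
        if (in_bootstrap && lost_streak[k] == cfg$max_lost_bootstrap + 1L)
          warning(sprintf(
            "identity %d lost for > %d consecutive bootstrap frames; training set degraded",
            k, cfg$max_lost_bootstrap))
      }
    }

    ## frame means for the next frame's features
    acc_df <- do.call(rbind, accepted)
    if (!is.null(acc_df) && nrow(acc_df) > 0) {
      ct <- cos(acc_df$theta) / sin(acc_df$theta)
      prev_means <- c(rho = mean(acc_df$rho), cot = mean(ct))
    }

    ## retrain at the end of the bootstrap, then every s frames
    if (n == cfg$bootstrap_len ||
        (n > cfg$bootstrap_len &&
         (n - cfg$bootstrap_len) %% cfg$s == 0)) {
      ensemble <- do_retrain(n)
      last_retrain <- n
    }
  }

  tr_mat <- tr_mat[seq_len(tr_n), , drop = FALSE]
  out <- data.frame(frame = as.integer(tr_mat[, "frame"]),
                    identity = as.integer(tr_mat[, "identity"]),
                    rho = tr_mat[, "rho"], theta = tr_mat[, "theta"],
                    b = tr_mat[, "b"], L = tr_mat[, "L"],
                    rss = tr_mat[, "rss"],
                    status = status_levels[tr_mat[, "status_code"]],
                    valid = tr_valid[seq_len(tr_n)])
  structure(list(trace = out,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(frame = integer(),
                                          identity = integer(),
                                          event = character(),
                                          uid = numeric()),
                 flagged = if (length(flagged)) do.call(rbind, flagged)
                           else data.frame(frame = integer(),
                                           identity = integer(),
                                           uid = numeric(),
                                           reason = character()),
                 retrains = retrains, n_identities = N, cfg = cfg),
            class = "whisker_tracks")
}

#' Bootstrap-only tracking
#'
#' Runs the Kalman-plus-assignment tracker over the first frames of a
#' detection sequence (no classifier), returning the labeled trace and the
#' initial training set for the recognizer. Equivalent to [track_whiskers()]
#' with the bootstrap spanning all supplied frames.
#'
#' @param detections list of per-frame detection data frames
#' @param cfg a [tracker_config]; its `bootstrap_len` is stretched to cover
#'   all supplied frames
#' @return a `whisker_tracks` object (its training window is in `retrains`)
#' @export
bootstrap_tracks <- function(detections, cfg = tracker_config()) {
  cfg$bootstrap_len <- length(detections)
  track_whiskers(detections, cfg)
}
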