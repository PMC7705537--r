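## Linear Kalman filter over the whisker state
## (rho, theta, rho_dot, theta_dot, b, L): constant velocity on (rho, theta),
## random walk on (b, L). Time step = 1 frame.

kalman_matrices <- function(cfg) {
  F <- diag(6)
  F[1, 3] <- 1
  F[2, 4] <- 1
  Q <- diag(cfg$process_noise^2)
  R <- diag(cfg$measurement_noise^2)
  H <- matrix(0, 4, 6)
  H[1, 1] <- 1; H[2, 2] <- 1; H[3, 5] <- 1; H[4, 6] <- 1
  list(F = F, Q = Q, R = R, H = H)
}

#' Initialize a per-identity Kalman track state
#'
#' @param params a [whisker_params] (or list with `rho`, `theta`, `b`, `L`)
#' @param identity integer identity label (fixed for the life of the track)
#' @param frame frame index of the first observation
#' @param cfg a [tracker_config]
#' @return object of class `track_state` with the state mean/covariance,
#'   `status` (`"tracked"`, `"lost"` or `"estimated"`) and `last_seen`
#' @export
kalman_init <- function(params, identity, frame, cfg) {
  mean <- c(params$rho, params$theta, 0, 0, params$b, params$L)
  cov <- diag(c(cfg$measurement_noise[1]^2, cfg$measurement_noise[2]^2,
                cfg$init_velocity_var, cfg$init_velocity_var / 100,
                cfg$measurement_noise[3]^2, cfg$measurement_noise[4]^2))
  structure(list(identity = as.integer(identity), mean = mean, cov = cov,
                 status = "tracked", last_seen = as.integer(frame),
                 mats = kalman_matrices(cfg)),
            class = "track_state")
}

#' One-frame Kalman prediction
#'
#' Constant-velocity prediction for (`rho`, `theta`), random walk for (`b`,
#' `L`); covariance propagated with additive process noise.
#'
#' @param state a `track_state`
#' @return the state advanced by one frame; the predicted measurement is
#'   available via [kalman_measurement()]
#' @export
kalman_predict <- function(state) {
  m <- state$mats
  state$mean <- drop(m$F %*% state$mean)
  state$cov <- m$F %*% state$cov %*% t(m$F) + m$Q
  state
}

#' Measurement-space view of a track state
#'
#' @param state a `track_state`
#' @return named vector (`rho`, `theta`, `b`, `L`)
#' @export
kalman_measurement <- function(state) {
  c(rho = state$mean[1], theta = state$mean[2], b = state$mean[5],
    L = state$mean[6])
}

#' Kalman measurement update
#'
#' @param state a `track_state` (already predicted to the current frame)
#' @param meas measurement vector or list with `rho`, `theta`, `b`, `L`
#' @param frame frame index of the measurement
#' @return updated state
#' @export
kalman_update <- function(state, meas, frame = state$last_seen + 1L) {
  m <- state$mats
  z <- c(meas$rho, meas$theta, meas$b, meas$L)
  y <- z - drop(m$H %*% state$mean)
  S <- m$H %*% state$cov %*% t(m$H) + m$R
  K <- state$cov %*% t(m$H) %*% solve(S)
  state$mean <- state$mean + drop(K %*% y)
  state$cov <- (diag(6) - K %*% m$H) %*% state$cov
  state$last_seen <- as.integer(frame)
  state$status <- "tracked"
  state
}
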