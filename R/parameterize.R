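#' Four-parameter whisker description
#'
#' A whisker in one frame is summarized by the tuple (`rho`, `theta`, `b`,
#' `L`) relative to a snout reference line: `rho` is the base position along
#' the line (px), `theta` the base angle relative to the line (radians, open
#' interval (0, pi)), `b` the bending coefficient of the quadratic deviation
#' model `d = b * x^2` (px^-1, with `x` the distance along the whisker chord
#' from the snout line and `d` the perpendicular deviation), and `L` the
#' straight-line base-to-tip distance (px).
#'
#' @param rho,theta,b,L numeric scalars, see description
#' @param rss residual sum of squares of the fit (px^2), `NA` if not fitted
#' @param frame frame index, `NA` if not attached to a frame
#' @param valid logical, `FALSE` when a fit failed to converge
#' @return object of class `whisker_params`
#' @export
whisker_params <- function(rho, theta, b, L, rss = NA_real_,
                           frame = NA_integer_, valid = TRUE) {
  stopifnot(is.finite(rho), is.finite(theta), is.finite(b), is.finite(L),
            L > 0)
  structure(list(rho = unname(rho), theta = unname(theta), b = unname(b),
                 L = unname(L), rss = unname(rss), frame = frame,
                 valid = valid),
            class = "whisker_params")
}

#' @export
print.whisker_params <- function(x, ...) {
  cat(sprintf(
    "whisker: rho = %.2f px, theta = %.4f rad (%.1f deg), b = %.2e 1/px, L = %.1f px\n",
    x$rho, x$theta, x$theta * 180 / pi, x$b, x$L))
  invisible(x)
}

## chord coordinate at which the base-to-tip distance reaches L:
## x^2 + b^2 x^4 = L^2
chord_end <- function(b, L) {
  if (abs(b) < 1e-12) return(L)
  sqrt((sqrt(1 + 4 * b^2 * L^2) - 1) / (2 * b^2))
}

#' Evaluate the whisker forward model
#'
#' Samples the curve implied by a parameter tuple: starting at snout-line
#' position `rho`, proceeding at angle `theta`, offset perpendicular to the
#' launch direction by `b * x^2` at chord distance `x`, stopping where the
#' straight base-to-tip distance reaches `L`.
#'
#' @param params a [whisker_params] object (or list with the same fields)
#' @param snout a [snout_line]
#' @param n_samples number of curve samples
#' @return an `n_samples` x 2 matrix of image points (columns `x`, `y`)
#' @export
whisker_curve <- function(params, snout, n_samples = 100) {
  stopifnot(inherits(snout, "snout_line"))
  th <- params$theta
  dirv <- cos(th) * snout$u + sin(th) * snout$n
  perp <- -sin(th) * snout$u + cos(th) * snout$n
  P <- snout$p0 + params$rho * snout$u
  xe <- chord_end(params$b, params$L)
  x <- seq(0, xe, length.out = n_samples)
  d <- params$b * x^2
  cbind(x = P[1] + x * dirv[1] + d * perp[1],
        y = P[2] + x * dirv[2] + d * perp[2])
}

## chord/deviation coordinates of points relative to (rho, theta)
chord_coords <- function(xy, rho, theta, snout) {
  dirv <- cos(theta) * snout$u + sin(theta) * snout$n
  perp <- -sin(theta) * snout$u + cos(theta) * snout$n
  P <- snout$p0 + rho * snout$u
  rx <- xy[, 1] - P[1]
  ry <- xy[, 2] - P[2]
  list(x = rx * dirv[1] + ry * dirv[2],
       d = rx * perp[1] + ry * perp[2])
}

#' Fit the four-parameter model to a whisker cluster
#'
#' Nonlinear least squares of the forward model against the cluster's
#' centerline points. The residual is the perpendicular deviation mismatch at
#' matched chord coordinate, `d_i - b * x_i^2`, with `x_i`, `d_i` measured in
#' the frame defined by (`rho`, `theta`). Initialization uses a straight-line
#' fit of the basal section (giving `theta0` and the snout-line intercept
#' `rho0`), `b0 = 0`. `L` is, by definition, the Euclidean base-to-tip
#' distance of the cluster and is not part of the optimization.
#'
#' @param cluster a [whisker_cluster] (or any object with a `points` data
#'   frame carrying `x`, `y`)
#' @param snout a [snout_line]
#' @param max_iter maximum optimizer iterations
#' @param tol relative convergence tolerance on the parameter step
#' @param init_len arclength of the basal section used for initialization (px)
#' @return a [whisker_params]; `valid = FALSE` if the fit did not converge
#' @export
fit_whisker <- function(cluster, snout, max_iter = 100, tol = 1e-8,
                        init_len = 20) {
  pts <- cluster$points
  if (nrow(pts) < 5) stop("fit_whisker needs a cluster with >= 5 points")
  xy <- cbind(pts$x, pts$y)
  ## orient base -> tip by distance to the snout line
  if (abs(snout_dist(snout, xy[1, ])) > abs(snout_dist(snout, xy[nrow(xy), ])))
    xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  base <- xy[1, ]; tip <- xy[nrow(xy), ]
  L <- sqrt(sum((tip - base)^2))

  ## init: straight fit of the basal section
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  sel <- which(s <= max(init_len, s[min(5, length(s))]))
  if (length(sel) < 2) sel <- seq_len(min(5, nrow(xy)))
  bs <- xy[sel, , drop = FALSE]
  ctr <- colMeans(bs)
  ev <- eigen(cov(bs), symmetric = TRUE)$vectors[, 1]
  if (sum(ev * (tip - base)) < 0) ev <- -ev
  th0 <- atan2(sum(ev * snout$n), sum(ev * snout$u))
  th0 <- min(max(th0, 1e-3), pi - 1e-3)
  ## snout-line intercept of the basal line: ctr + t*ev, solve n-component = 0
  nc <- snout_dist(snout, ctr)
  ev_n <- sum(ev * snout$n)
  t0 <- if (abs(ev_n) > 1e-9) -nc / ev_n else 0
  rho0 <- snout_rho(snout, ctr + t0 * ev)

  resfun <- function(par) {
    cc <- chord_coords(xy, par[1], par[2], snout)
    cc$d - par[3] * cc$x^2
  }
  fit <- minpack.lm::nls.lm(
    par = c(unname(rho0), unname(th0), 0),
    fn = resfun,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = tol, ptol = tol))
  par <- fit$par
  th <- par[2] %% pi
  ok <- fit$info %in% 1:4 && th > 0 && th < pi && is.finite(par[1])
  whisker_params(rho = par[1], theta = if (ok) th else max(min(th, pi - 1e-6), 1e-6),
                 b = par[3], L = L,
                 rss = sum(fit$fvec^2), valid = ok)
}
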