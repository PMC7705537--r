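#' Snout reference line
#'
#' Whisker base position `rho` and base angle `theta` are measured against a
#' straight reference line drawn along the snout edge. The line is given by
#' two endpoints in image coordinates (`x` along columns, `y` along rows, both
#' 1-based pixel centers). The unit normal points away from the snout, toward
#' the whiskers; by default it is the along-line direction rotated by -90
#' degrees, and `side_point` (any point known to lie on the whisker side)
#' can be given to fix the orientation explicitly.
#'
#' @param p0,p1 numeric length-2 vectors `(x, y)`; the endpoints. Must differ.
#' @param side_point optional `(x, y)` point on the whisker side of the line.
#' @return an object of class `snout_line` with fields `p0`, `p1`, the
#'   along-line unit vector `u` and the whisker-side unit normal `n`.
#' @examples
#' sl <- snout_line(c(80, 20), c(80, 460))
#' snout_rho(sl, c(80, 120))   # position along the line
#' snout_dist(sl, c(100, 120)) # signed distance, positive on whisker side
#' @export
snout_line <- function(p0, p1, side_point = NULL) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 2, length(p1) == 2)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("snout line endpoints must differ")
  u <- d / len
  n <- c(u[2], -u[1])
  if (!is.null(side_point)) {
    if (sum((as.numeric(side_point) - p0) * n) < 0) n <- -n
  }
  structure(list(p0 = p0, p1 = p1, u = u, n = n, length = len),
            class = "snout_line")
}

#' @describeIn snout_line position of points along the line (px from `p0`).
#'   `xy` is a length-2 vector or a 2-column matrix.
#' @param snout a `snout_line`
#' @param xy point(s), length-2 vector or 2-column (x, y) matrix
#' @export
snout_rho <- function(snout, xy) {
  xy <- rbind(xy)
  (xy[, 1] - snout$p0[1]) * snout$u[1] + (xy[, 2] - snout$p0[2]) * snout$u[2]
}

#' @describeIn snout_line signed perpendicular distance of points from the
#'   line; positive on the whisker side.
#' @export
snout_dist <- function(snout, xy) {
  xy <- rbind(xy)
  (xy[, 1] - snout$p0[1]) * snout$n[1] + (xy[, 2] - snout$p0[2]) * snout$n[2]
}

#' @describeIn snout_line image point at position `rho` along the line.
#' @param rho position(s) along the line in px
#' @export
snout_point <- function(snout, rho) {
  cbind(x = snout$p0[1] + rho * snout$u[1],
        y = snout$p0[2] + rho * snout$u[2])
}
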