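#' Gaussian partial derivatives of a frame
#'
#' Convolves the image with sampled Gaussian-derivative kernels at scale
#' `sigma` (separable, reflected boundary), giving the five partial
#' derivatives needed for second-order ridge analysis. The kernels are
#' normalized so constant, linear and quadratic images produce exact
#' responses.
#'
#' @param image cleaned intensity matrix (whiskers bright)
#' @param sigma derivative scale in px; for a ridge of Gaussian cross-section
#'   sd `w` choose `sigma >= w / sqrt(3)`
#' @return object of class `derivative_stack`: matrices `rx`, `ry`, `rxx`,
#'   `rxy`, `ryy` plus `sigma`
#' @export
compute_derivatives <- function(image, sigma = 1.5) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  d <- cpp_gaussian_derivatives(image, sigma)
  d$sigma <- sigma
  class(d) <- "derivative_stack"
  d
}

#' Ridge-strength threshold from a calibration frame
#'
#' The ridge strength at a pixel is the magnitude of the negative Hessian
#' eigenvalue (0 where there is none). The default detection threshold is a
#' high quantile of the nonzero strengths of a calibration frame, separating
#' whisker ridges from noise-induced curvature.
#'
#' The default (`"fraction"`) anchors the threshold at a fraction of a high
#' strength quantile: whisker cores form a narrow band of strong strengths,
#' so `frac * quantile(s, q)` lands below the band but above fur and noise
#' curvature regardless of how much of the frame the whiskers occupy. A
#' plain high quantile (`"quantile"`) is also offered but lands inside the
#' whisker band whenever whiskers dominate the nonzero pixels (after
#' cleaning, the background is mostly exactly zero); `"otsu"` splits the
#' positive log-strengths in two, which separates noise from everything
#' else but keeps fur.
#'
#' @param derivs a `derivative_stack`
#' @param method `"fraction"`, `"otsu"` or `"quantile"`
#' @param q reference quantile in (0, 1)
#' @param frac fraction of the reference quantile (`"fraction"` method)
#' @return scalar threshold (intensity / px^2)
#' @export
calibrate_strength_threshold <- function(derivs,
                                         method = c("fraction", "otsu",
                                                    "quantile"),
                                         q = NULL, frac = 0.4) {
  method <- match.arg(method)
  s <- cpp_ridge_strength(derivs$rxx, derivs$rxy, derivs$ryy)
  s <- s[s > 0]
  if (length(s) == 0) return(Inf)
  if (method == "quantile") return(unname(quantile(s, if (is.null(q)) 0.99 else q)))
  if (method == "otsu") return(10^otsu_split(log10(s)))
  frac * unname(quantile(s, if (is.null(q)) 0.995 else q))
}

## 1-D Otsu threshold on a numeric sample
otsu_split <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  h <- as.numeric(tabulate(pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1,
                                n_bins), n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w <- cumsum(h); m <- cumsum(h * mids)
  wt <- w[n_bins]; mt <- m[n_bins]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Detect sub-pixel whisker centerline points
#'
#' Per pixel, the 2x2 Hessian of the Gaussian-smoothed image is
#' eigen-decomposed; the eigenvector of the most negative eigenvalue is the
#' ridge normal. The zero of the first directional derivative of the local
#' second-order Taylor model along that normal gives the sub-pixel centerline
#' position; it is accepted only if it falls within the pixel (normal offset
#' at most 0.5 px) and the eigenvalue magnitude reaches `min_strength`. Each
#' pixel contributes at most one point; pixels are independent, so the result
#' does not depend on processing order.
#'
#' @param derivs a `derivative_stack`
#' @param min_strength minimum ridge strength (intensity / px^2); `NULL`
#'   calibrates via [calibrate_strength_threshold()]
#' @param method,q calibration options used when `min_strength` is `NULL`
#' @return data frame with columns `x`, `y` (sub-pixel image coordinates),
#'   `direction` (tangent angle in `[0, pi)`), `strength`, `row`, `col`
#' @export
detect_centerline_points <- function(derivs, min_strength = NULL,
                                     method = "fraction", q = NULL) {
  stopifnot(inherits(derivs, "derivative_stack"))
  if (is.null(min_strength))
    min_strength <- calibrate_strength_threshold(derivs, method, q)
  m <- cpp_ridge_points(derivs$rx, derivs$ry, derivs$rxx, derivs$rxy,
                        derivs$ryy, min_strength)
  out <- as.data.frame(m)
  out$row <- as.integer(out$row)
  out$col <- as.integer(out$col)
  out
}
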