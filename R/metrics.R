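## A trace table is a data frame with columns frame, identity, rho, theta,
## b, L, rss, status, valid; rows with valid == FALSE (Kalman estimates) are
## not part of the tracker output and are excluded by all metrics.

valid_trace <- function(trace) {
  if (!is.null(trace$valid)) trace[trace$valid, , drop = FALSE] else trace
}

#' Tracked whiskers per frame
#'
#' @param trace a trace table
#' @param n_frames total number of frames (defaults to the max frame index)
#' @return list: `counts` (data frame `frame`, `count`, zero-filled),
#'   `mean`, `sd`, `histogram` (table of counts)
#' @export
whiskers_per_frame <- function(trace, n_frames = NULL) {
  tr <- valid_trace(trace)
  if (is.null(n_frames))
    n_frames <- if (nrow(trace)) max(trace$frame) else 0L
  counts <- integer(n_frames)
  if (nrow(tr)) {
    tb <- table(factor(tr$frame, levels = seq_len(n_frames)))
    counts <- as.integer(tb)
  }
  df <- data.frame(frame = seq_len(n_frames), count = counts)
  list(counts = df, mean = if (n_frames) mean(counts) else NA_real_,
       sd = if (n_frames > 1) sd(counts) else NA_real_,
       histogram = table(counts))
}

#' Detection ratio per identity
#'
#' Percentage of frames in which an identity has a valid entry.
#'
#' @param trace a trace table
#' @param identity identity label(s); `NULL` = all identities present
#' @param n_frames total number of frames (defaults to the max frame index)
#' @return named numeric vector of percentages in `[0, 100]`
#' @export
detection_ratio <- function(trace, identity = NULL, n_frames = NULL) {
  tr <- valid_trace(trace)
  if (is.null(n_frames))
    n_frames <- if (nrow(trace)) max(trace$frame) else 0L
  if (is.null(identity)) identity <- sort(unique(trace$identity))
  out <- vapply(identity, function(k)
    100 * sum(tr$identity == k) / n_frames, 0)
  names(out) <- identity
  out
}

#' Signal-to-noise ratio of an angle trace
#'
#' Whisking (up to ~30 Hz) is far slower than the frame rate, so smoothing
#' the angle trace separates true movement from tracker noise. The smoothed
#' component is a quadratic Savitzky-Golay fit over a centered window
#' (default 11 frames, the odd-window rendering of a 10-frame choice); the
#' noise is the residual. SNR (dB) is `10 log10` of the ratio of the
#' mean-removed signal power to the noise power. Because a local polynomial
#' fit absorbs part of any white noise into the smooth (and the residual
#' correspondingly under-reports it), both powers are corrected using the
#' filter's known white-noise gains, which makes the estimate agree with
#' the true component power ratio across a wide SNR range. Missing samples
#' (`NA`) split the trace into segments; segments shorter than the window
#' are excluded.
#'
#' @param theta numeric angle trace (radians), `NA` for missing frames
#' @param window Savitzky-Golay window length (odd)
#' @param order polynomial order
#' @return SNR in dB; `Inf` (with attribute `zero_noise = TRUE`) when the
#'   residual is identically zero
#' @export
compute_snr <- function(theta, window = 11, order = 2) {
  stopifnot(window %% 2 == 1, order < window)
  idx <- which(!is.na(theta))
  if (length(idx) == 0) return(NA_real_)
  ## white-noise gains of the centered smoothing filter: the smooth keeps
  ## sum(w^2) of the noise variance, the residual keeps 1 - 2 w0 + sum(w^2)
  w <- signal::sgolay(p = order, n = window)[(window + 1) / 2, ]
  w0 <- w[(window + 1) / 2]
  beta <- sum(w^2)
  alpha <- 1 - 2 * w0 + beta
  ## contiguous runs of valid samples
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  sig2 <- 0; noise2 <- 0; n_used <- 0L; any_seg <- FALSE
  for (r in runs) {
    if (length(r) < window) next
    any_seg <- TRUE
    x <- theta[r]
    sm <- signal::sgolayfilt(x, p = order, n = window)
    res <- x - sm
    sig2 <- sig2 + sum((sm - mean(sm))^2)
    noise2 <- noise2 + sum(res^2)
    n_used <- n_used + length(r)
  }
  if (!any_seg) return(NA_real_)
  scale0 <- max(sig2, noise2)
  if (noise2 <= 1e-20 * max(scale0, 1)) {
    out <- Inf
    attr(out, "zero_noise") <- TRUE
    return(out)
  }
  noise_hat <- noise2 / alpha
  sig_hat <- max(sig2 - beta * noise_hat, .Machine$double.xmin)
  10 * log10(sig_hat / noise_hat)
}

#' Identity switches against ground truth
#'
#' Maps, per frame, each tracked identity to the ground-truth whisker nearest
#' in normalized parameter space. A switch is a change of that mapping
#' between an identity's consecutive valid frames; consistency is the
#' fraction of an identity's frames carrying its modal mapping.
#'
#' @param trace a trace table
#' @param truth ground-truth table (`frame`, `whisker`, `rho`, `theta`, `b`,
#'   `L`), e.g. `scene$truth` from [generate_scene()]
#' @return list: `switches` (total count), `consistency` (overall fraction in
#'   `[0, 1]`), `per_identity` (data frame), `mapping` (per valid trace row)
#' @export
identity_switches <- function(trace, truth) {
  tr <- valid_trace(trace)
  if (nrow(tr) == 0)
    return(list(switches = 0L, consistency = NA_real_,
                per_identity = data.frame(), mapping = data.frame()))
  sc <- c(rho = max(sd(truth$rho), 1e-9), theta = max(sd(truth$theta), 1e-9),
          b = max(sd(truth$b), 1e-9), L = max(sd(truth$L), 1e-9))
  map <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    gt <- truth[truth$frame == tr$frame[i], , drop = FALSE]
    d <- ((gt$rho - tr$rho[i]) / sc["rho"])^2 +
         ((gt$theta - tr$theta[i]) / sc["theta"])^2 +
         ((gt$b - tr$b[i]) / sc["b"])^2 +
         ((gt$L - tr$L[i]) / sc["L"])^2
    map[i] <- gt$whisker[which.min(d)]
  }
  mapping <- data.frame(frame = tr$frame, identity = tr$identity,
                        truth_whisker = map)
  per <- do.call(rbind, lapply(sort(unique(mapping$identity)), function(k) {
    mk <- mapping[mapping$identity == k, , drop = FALSE]
    mk <- mk[order(mk$frame), ]
    sw <- sum(diff(mk$truth_whisker) != 0)
    modal <- as.integer(names(which.max(table(mk$truth_whisker))))
    data.frame(identity = k, n = nrow(mk), switches = sw,
               modal_whisker = modal,
               consistency = mean(mk$truth_whisker == modal))
  }))
  list(switches = sum(per$switches),
       consistency = sum(per$n * per$consistency) / sum(per$n),
       per_identity = per, mapping = mapping)
}
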