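## Independent reference implementations used as oracles. These deliberately
## share no code with the package internals.

## Reference DBSCAN via full distance matrix (n <= a few hundred).
## Returns integer labels, 0 = noise. Border points join the cluster of the
## first core neighbor in index order (the package uses the same rule).
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (q in nb[[j]]) {
        if (labels[q] == 0) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

## Reference mutual-neighbor graph components (matches the documented rule:
## per point, one best candidate per tangent sign within the Chebyshev-2
## pixel shell and the angular tolerance; edges require mutual proposal).
brute_mutual_components <- function(pts, angle_tol = pi / 4) {
  n <- nrow(pts)
  prop <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    tx <- cos(pts$direction[i]); ty <- sin(pts$direction[i])
    for (s in c(1, -1)) {
      cand <- which(abs(pts$row - pts$row[i]) <= 2 &
                    abs(pts$col - pts$col[i]) <= 2 &
                    seq_len(n) != i)
      best <- NA_integer_; bestd <- Inf
      for (j in cand) {
        dx <- pts$x[j] - pts$x[i]; dy <- pts$y[j] - pts$y[i]
        proj <- s * (dx * tx + dy * ty)
        dd <- sqrt(dx^2 + dy^2)
        if (proj <= 0 || dd < 1e-12) next
        if (proj / dd < cos(angle_tol)) next
        if (dd < bestd - 1e-12 || (abs(dd - bestd) <= 1e-12 && j < best)) {
          bestd <- dd; best <- j
        }
      }
      prop[i, (3 - s) / 2] <- best
    }
  }
  ## mutual edges -> components by repeated flood fill
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n)) for (s in 1:2) {
    j <- prop[i, s]
    if (!is.na(j) && any(prop[j, ] == i, na.rm = TRUE)) {
      adj[[i]] <- union(adj[[i]], j)
      adj[[j]] <- union(adj[[j]], i)
    }
  }
  labels <- integer(n); cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] != 0) next
      labels[j] <- cl
      queue <- c(queue, adj[[j]][labels[adj[[j]]] == 0])
    }
  }
  labels
}

## Exhaustive minimum-cost assignment (small matrices); when rows outnumber
## columns the problem is transposed so the best row subset is explored too
brute_assignment <- function(cost) {
  if (nrow(cost) > ncol(cost)) {
    res <- brute_assignment(t(cost))
    assn <- rep(NA_integer_, nrow(cost))
    assn[res$assignment] <- seq_along(res$assignment)
    return(list(cost = res$cost, assignment = assn))
  }
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  cols <- combn(seq_len(m), min(n, m), simplify = FALSE)
  best <- Inf; best_assn <- NULL
  for (cs in cols) for (p in perms(cs)) {
    idx <- cbind(seq_len(length(p)), p)
    tot <- sum(cost[idx])
    if (tot < best) { best <- tot; best_assn <- p }
  }
  list(cost = best, assignment = best_assn)
}

## Partition equality up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

## Analytic noiseless ridge image: Gaussian profile around a straight
## segment, rendered from the exact point-to-segment distance (independent
## of the package renderer).
analytic_ridge_image <- function(nr, nc, p0, p1, width_fwhm, amp) {
  sd <- width_fwhm / (2 * sqrt(2 * log(2)))
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr), nc), nr, nc)
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((xg - p0[1]) * vx + (yg - p0[2]) * vy) / len2, 0), 1)
  d2 <- (xg - (p0[1] + t * vx))^2 + (yg - (p0[2] + t * vy))^2
  amp * exp(-d2 / (2 * sd^2))
}

## Synthetic labeled detection streams (no rendering): N whiskers rotating
## about fixed pivots with sinusoidal whisking plus Gaussian jitter.
make_detection_stream <- function(n_frames, pivots, rest, amp, freq = 8,
                                  fps = 1000, L = NULL, b = 1e-3,
                                  jitter = c(rho = 0.2, theta = 0.002,
                                             b = 2e-5, L = 0.5),
                                  pivot_depth = 40, seed = 1,
                                  drop = NULL) {
  N <- length(pivots)
  if (is.null(L)) L <- seq(150, 150 + 10 * (N - 1), by = 10)
  withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      t <- (i - 1) / fps
      th <- rest + amp * sin(2 * pi * freq * t)
      rho <- pivot_depth / tan(th) + pivots
      keep <- seq_len(N)
      if (!is.null(drop)) {
        dr <- drop[drop$frame == i, "whisker"]
        keep <- setdiff(keep, dr)
      }
      data.frame(
        rho = rho[keep] + rnorm(length(keep), 0, jitter["rho"]),
        theta = th[keep] + rnorm(length(keep), 0, jitter["theta"]),
        b = b + rnorm(length(keep), 0, jitter["b"]),
        L = L[keep] + rnorm(length(keep), 0, jitter["L"]),
        truth = keep)
    })
  })
}
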