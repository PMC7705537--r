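#' Clustering configuration
#'
#' @param method initial clustering algorithm: `"dbscan"` (density-based;
#'   robust to rough or interrupted centerlines) or `"steger"` (mutual
#'   nearest-neighbor linking along local tangents; separates crossing
#'   whiskers when the centerline is smooth)
#' @param dbscan_eps neighborhood radius (px)
#' @param dbscan_min_pts minimum neighborhood size (including the point) for
#'   a core point
#' @param steger_angle_tol angular tolerance (radians) between a point's
#'   tangent and the displacement to a candidate neighbor
#' @param stitch_fit_len tip-section arclength (px) linearized when stitching
#' @param stitch_max_dist maximum distance (px) of a candidate base point
#'   from the extended tip line
#' @param stitch_max_gap maximum along-line gap (px) bridged by stitching
#' @param stitch_max_angle maximum angle (radians) between the extended tip
#'   line and the candidate cluster's own basal direction
#' @param min_whisker_len clusters shorter than this (px) are discarded as
#'   fur
#' @param snout_attach_dist a cluster is snout-connected when its base point
#'   is within this distance (px) of the snout line
#' @return a `cluster_config` list
#' @export
cluster_config <- function(method = c("dbscan", "steger"), dbscan_eps = 2.5,
                           dbscan_min_pts = 3,
                           steger_angle_tol = deg2rad(45),
                           stitch_fit_len = 20, stitch_max_dist = 3,
                           stitch_max_gap = 30,
                           stitch_max_angle = deg2rad(30),
                           min_whisker_len = 40, snout_attach_dist = 10) {
  method <- match.arg(method)
  stopifnot(dbscan_eps > 0, dbscan_min_pts >= 1, stitch_fit_len > 0,
            stitch_max_dist > 0, stitch_max_gap > 0, min_whisker_len >= 0,
            snout_attach_dist > 0)
  structure(list(method = method, dbscan_eps = dbscan_eps,
                 dbscan_min_pts = as.integer(dbscan_min_pts),
                 steger_angle_tol = steger_angle_tol,
                 stitch_fit_len = stitch_fit_len,
                 stitch_max_dist = stitch_max_dist,
                 stitch_max_gap = stitch_max_gap,
                 stitch_max_angle = stitch_max_angle,
                 min_whisker_len = min_whisker_len,
                 snout_attach_dist = snout_attach_dist),
            class = "cluster_config")
}

#' One cluster of centerline points hypothesized to be a whisker
#'
#' Points are kept ordered along the curve. `copied` flags points duplicated
#' from another cluster by [resolve_base_overlap()].
#'
#' @param points data frame with at least `x`, `y` (and usually `direction`,
#'   `strength`); optionally a logical `copied` column
#' @return object of class `whisker_cluster` with fields `points`,
#'   `length_px`, `base_point`, `tip_point`
#' @export
whisker_cluster <- function(points) {
  if (is.null(points$copied)) points$copied <- FALSE
  n <- nrow(points)
  len <- if (n >= 2)
    sum(sqrt(diff(points$x)^2 + diff(points$y)^2)) else 0
  structure(list(points = points, length_px = len,
                 base_point = c(points$x[1], points$y[1]),
                 tip_point = c(points$x[n], points$y[n])),
            class = "whisker_cluster")
}

## order points along the curve by projection on the first principal axis
order_points_along_curve <- function(points) {
  if (nrow(points) < 3) return(points)
  xy <- cbind(points$x, points$y)
  ctr <- colMeans(xy)
  ev <- eigen(cov(xy), symmetric = TRUE)$vectors[, 1]
  proj <- (xy[, 1] - ctr[1]) * ev[1] + (xy[, 2] - ctr[2]) * ev[2]
  points[order(proj), , drop = FALSE]
}

## orient a cluster so its first point (base) is the endpoint nearer the snout
orient_cluster <- function(cl, snout) {
  pts <- cl$points
  n <- nrow(pts)
  d0 <- abs(snout_dist(snout, c(pts$x[1], pts$y[1])))
  d1 <- abs(snout_dist(snout, c(pts$x[n], pts$y[n])))
  if (d1 < d0) pts <- pts[rev(seq_len(n)), , drop = FALSE]
  rownames(pts) <- NULL
  whisker_cluster(pts)
}

#' Density-based clustering of centerline points
#'
#' Standard density-based clustering on the sub-pixel (x, y) positions:
#' points within `eps` of enough neighbors form connected clusters; sparse
#' points are discarded as noise. Each cluster is then ordered along its
#' principal curve.
#'
#' @param points data frame from [detect_centerline_points()]
#' @param eps neighborhood radius (px)
#' @param min_pts core-point neighborhood size (including the point itself)
#' @return list of [whisker_cluster]
#' @export
cluster_dbscan <- function(points, eps = 2.5, min_pts = 3) {
  stopifnot(eps > 0)
  if (nrow(points) == 0) return(list())
  labels <- cpp_dbscan(points$x, points$y, eps, as.integer(min_pts))
  lapply(sort(unique(labels[labels > 0])), function(l) {
    whisker_cluster(order_points_along_curve(points[labels == l, , drop = FALSE]))
  })
}

#' Direction-based mutual-neighbor clustering
#'
#' Each point proposes at most one neighbor forward and one backward along
#' its local tangent, searching its 8-neighborhood and the ring one pixel
#' further (so a single missing point does not break a chain), within an
#' angular tolerance. Two points are linked only when they mutually propose
#' each other; clusters are the connected components of this graph. Because
#' links follow directions, two crossing whiskers stay separate as long as
#' their tangents differ at the junction.
#'
#' @param points data frame from [detect_centerline_points()] (needs `row`,
#'   `col`, `direction`)
#' @param angle_tol angular tolerance in radians
#' @param dims image dimensions `c(rows, cols)`; inferred from the points
#'   when omitted
#' @return list of [whisker_cluster]
#' @export
cluster_steger <- function(points, angle_tol = deg2rad(45), dims = NULL) {
  if (nrow(points) == 0) return(list())
  if (is.null(dims)) dims <- c(max(points$row), max(points$col))
  res <- cpp_steger_links(points$x, points$y, points$row, points$col,
                          points$direction, dims[1], dims[2], angle_tol)
  labels <- res$labels
  ## adjacency (mutual links only; every point has degree <= 2, so each
  ## component is a path, or rarely a cycle)
  adj <- vector("list", nrow(points))
  if (nrow(res$edges) > 0) for (e in seq_len(nrow(res$edges))) {
    i <- res$edges[e, 1]; j <- res$edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (l in sort(unique(labels))) {
    idx <- which(labels == l)
    ordered <- order_component_path(idx, adj)
    for (part in split_path_reversals(ordered, points))
      out[[length(out) + 1]] <-
        whisker_cluster(points[part, , drop = FALSE])
  }
  out
}

## order a path component by walking its links from an endpoint
order_component_path <- function(idx, adj) {
  if (length(idx) <= 2) return(idx)
  deg <- vapply(idx, function(i) length(adj[[i]]), 0L)
  start <- if (any(deg <= 1)) idx[which(deg <= 1)[1]] else min(idx)
  ordered <- integer(length(idx))
  ordered[1] <- start
  prev <- -1L
  for (k in seq_along(idx)[-1]) {
    nxt <- setdiff(adj[[ordered[k - 1]]], prev)
    if (length(nxt) == 0) {   # disconnected remainder (should not happen)
      rest <- setdiff(idx, ordered[seq_len(k - 1)])
      ordered[k:length(idx)] <- rest
      break
    }
    prev <- ordered[k - 1]
    ordered[k] <- nxt[1]
  }
  ordered
}

## cut a path where the traversal turns too sharply: mutual links can bridge
## two whiskers right at a shallow crossing, producing a path that runs up
## one whisker and folds back down the other. The turn is measured between
## windowed displacement vectors (+-4 points) so a fold spread over several
## blended junction points is still caught, while genuine whisker curvature
## (a few milliradians per px) stays far below the threshold.
split_path_reversals <- function(ordered, points, window = 4,
                                 max_turn = deg2rad(60)) {
  n <- length(ordered)
  if (n < 3) return(list(ordered))
  x <- points$x[ordered]; y <- points$y[ordered]
  turn <- numeric(n)
  for (i in 2:(n - 1)) {
    i0 <- max(1, i - window); i1 <- min(n, i + window)
    v1 <- c(x[i] - x[i0], y[i] - y[i0])
    v2 <- c(x[i1] - x[i], y[i1] - y[i])
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) next
    turn[i] <- acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1))
  }
  sharp <- turn > max_turn
  if (!any(sharp)) return(list(ordered))
  ## cut once per run of sharp turns, at the sharpest point
  runs <- rle(sharp)
  ends <- cumsum(runs$lengths)
  cuts <- integer(0)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    seg <- (ends[k] - runs$lengths[k] + 1):ends[k]
    cuts <- c(cuts, seg[which.max(turn[seg])])
  }
  bounds <- unique(c(0, cuts, n))
  parts <- lapply(seq_len(length(bounds) - 1), function(k)
    ordered[(bounds[k] + 1):bounds[k + 1]])
  parts[vapply(parts, length, 0L) > 0]
}

## total-least-squares line through a set of points: list(center, dir)
tls_line <- function(xy) {
  ctr <- colMeans(xy)
  if (nrow(xy) < 2) return(list(center = ctr, dir = c(1, 0)))
  ev <- eigen(cov(xy), symmetric = TRUE)$vectors[, 1]
  list(center = ctr, dir = ev / sqrt(sum(ev^2)))
}

## arclength-limited section from the tip (or base) of an oriented cluster
cluster_section <- function(cl, len, from = c("tip", "base")) {
  from <- match.arg(from)
  pts <- cl$points
  xy <- cbind(pts$x, pts$y)
  if (nrow(xy) < 2) return(xy)
  if (from == "tip") xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  keep <- which(s <= len)
  if (length(keep) < 2) keep <- seq_len(min(3, nrow(xy)))
  xy[keep, , drop = FALSE]
}

#' Stitch collinear cluster fragments
#'
#' Whisker occlusions and detection dropouts fragment a whisker into several
#' clusters. For every cluster long enough to linearize, a line is fit to its
#' tip section and extended tip-ward; clusters whose base point lies within
#' `stitch_max_dist` of that line, within `stitch_max_gap` along it, and
#' whose own basal direction agrees with the line (within
#' `stitch_max_angle`), are candidates. The candidate whose base point is
#' closest to the tip is merged (ties by lowest index), and the scan repeats
#' until no merge occurs.
#'
#' @param clusters list of [whisker_cluster]
#' @param cfg a [cluster_config]
#' @param snout a [snout_line] used to orient fragments base-to-tip
#' @return list of [whisker_cluster]
#' @export
stitch_clusters <- function(clusters, cfg, snout) {
  clusters <- lapply(clusters, orient_cluster, snout = snout)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= length(clusters)) {
      a <- clusters[[i]]
      if (a$length_px < cfg$stitch_fit_len) { i <- i + 1; next }
      sec <- cluster_section(a, cfg$stitch_fit_len, "tip")
      ln <- tls_line(sec)
      ## orient the line tip-ward (base -> tip of the section)
      tipdir <- a$tip_point - sec[nrow(sec), ]
      if (sum(tipdir^2) < 1e-12) tipdir <- a$tip_point - a$base_point
      if (sum(ln$dir * tipdir) < 0) ln$dir <- -ln$dir
      ## among candidates passing the gates, the best continuation minimizes
      ## the combined normalized deviation (distance gates alone cannot
      ## discriminate at a crossing, where two bases sit sub-pixel apart)
      best <- NULL; best_score <- Inf
      for (j in seq_along(clusters)) {
        if (j == i) next
        b <- clusters[[j]]
        w <- b$base_point - a$tip_point
        along <- sum(w * ln$dir)
        if (along <= -2 || along > cfg$stitch_max_gap) next
        wl <- b$base_point - ln$center
        perp <- abs(wl[1] * ln$dir[2] - wl[2] * ln$dir[1])
        if (perp > cfg$stitch_max_dist) next
        ## direction consistency of the candidate's basal section
        bsec <- cluster_section(b, cfg$stitch_fit_len, "base")
        bdir <- tls_line(bsec)$dir
        dang <- angle_diff_mod_pi(atan2(bdir[2], bdir[1]),
                                  atan2(ln$dir[2], ln$dir[1]))
        if (dang > cfg$stitch_max_angle) next
        score <- perp / cfg$stitch_max_dist + dang / cfg$stitch_max_angle +
          sqrt(sum(w^2)) / cfg$stitch_max_gap
        if (score < best_score - 1e-12) { best_score <- score; best <- j }
      }
      if (!is.null(best)) {
        pts <- rbind(clusters[[i]]$points, clusters[[best]]$points)
        clusters[[i]] <- orient_cluster(
          whisker_cluster(order_points_along_curve(pts)), snout)
        clusters[[best]] <- NULL
        merged <- TRUE
        i <- 1            # restart the scan after a merge
      } else i <- i + 1
    }
    if (!merged) break
  }
  clusters
}

#' Resolve whiskers that share a base segment
#'
#' When two whiskers fully overlap near the snout and diverge distally, the
#' lower whisker's cluster starts in mid-air. For each cluster whose base is
#' farther than `snout_attach_dist` from the snout line, its basal direction
#' is extrapolated toward the snout; if a snout-connected cluster has points
#' lying along that extrapolation (within `stitch_max_dist`), those points
#' are copied (flagged) onto the floating cluster so both reach the snout.
#'
#' @param clusters list of [whisker_cluster] (already stitched)
#' @param snout a [snout_line]
#' @param cfg a [cluster_config]
#' @return list of [whisker_cluster]
#' @export
resolve_base_overlap <- function(clusters, snout, cfg) {
  if (length(clusters) < 2) return(clusters)
  base_d <- vapply(clusters, function(cl)
    abs(snout_dist(snout, cl$base_point)), 0)
  for (i in seq_along(clusters)) {
    if (base_d[i] <= cfg$snout_attach_dist) next
    a <- clusters[[i]]
    ## only whisker-sized fragments qualify: copying a base segment onto a
    ## short fur chain would fabricate a duplicate whisker
    if (a$length_px < cfg$min_whisker_len) next
    sec <- cluster_section(a, cfg$stitch_fit_len, "base")
    ln <- tls_line(sec)
    ## orient toward the snout
    if (sum(ln$dir * snout$n) > 0) ln$dir <- -ln$dir
    ## find the donor whose curve the extrapolated base line approaches most
    ## closely on the snout side; copy that donor's base segment (junction
    ## down to the snout) so the floating cluster reaches the snout line
    best <- NULL; best_score <- Inf
    for (j in seq_along(clusters)) {
      if (j == i || base_d[j] > cfg$snout_attach_dist) next
      pts <- clusters[[j]]$points
      wl_x <- pts$x - a$base_point[1]
      wl_y <- pts$y - a$base_point[2]
      perp <- abs(wl_x * ln$dir[2] - wl_y * ln$dir[1])
      along <- wl_x * ln$dir[1] + wl_y * ln$dir[2]
      ## the junction must lie close beyond the orphan's base; a donor curve
      ## approached only far away is not a shared base
      cand <- which(along > 0 & along <= cfg$stitch_max_gap)
      if (length(cand) < 1) next
      hit <- cand[which.min(perp[cand])]
      if (perp[hit] > cfg$stitch_max_dist) next
      ## shared-base overlap implies near-parallel curves at the junction; a
      ## mere crossing (X-junction) has divergent directions and is excluded
      win <- max(1, hit - 3):min(nrow(pts), hit + 3)
      ddir <- tls_line(cbind(pts$x[win], pts$y[win]))$dir
      if (angle_diff_mod_pi(atan2(ddir[2], ddir[1]),
                            atan2(ln$dir[2], ln$dir[1])) >
          cfg$stitch_max_angle) next
      if (perp[hit] < best_score - 1e-12) {
        best_score <- perp[hit]
        seg_max <- abs(snout_dist(snout, c(pts$x[hit], pts$y[hit])))
        seg <- abs(snout_dist(snout, cbind(pts$x, pts$y))) <= seg_max
        best <- pts[seg, , drop = FALSE]
      }
    }
    if (!is.null(best)) {
      best$copied <- TRUE
      merged <- rbind(a$points, best)
      clusters[[i]] <- orient_cluster(
        whisker_cluster(order_points_along_curve(merged)), snout)
    }
  }
  clusters
}

#' Discard fur by length
#'
#' Fur hairs near the snout produce short centerline chains; whiskers are
#' long. Clusters shorter than `min_whisker_len` px are removed.
#'
#' @param clusters list of [whisker_cluster]
#' @param min_whisker_len length threshold (px)
#' @return filtered list
#' @export
filter_fur <- function(clusters, min_whisker_len = 40) {
  Filter(function(cl) cl$length_px >= min_whisker_len, clusters)
}

#' Full clustering chain
#'
#' Initial clustering (method per config), orientation, stitching, base
#' overlap resolution and fur filtering.
#'
#' @param points data frame from [detect_centerline_points()]
#' @param cfg a [cluster_config]
#' @param snout a [snout_line]
#' @param dims image dimensions `c(rows, cols)` (needed for the
#'   direction-based method)
#' @return list of [whisker_cluster]
#' @export
cluster_whiskers <- function(points, cfg, snout, dims = NULL) {
  clusters <- if (cfg$method == "dbscan")
    cluster_dbscan(points, cfg$dbscan_eps, cfg$dbscan_min_pts)
  else
    cluster_steger(points, cfg$steger_angle_tol, dims)
  clusters <- stitch_clusters(clusters, cfg, snout)
  clusters <- resolve_base_overlap(clusters, snout, cfg)
  filter_fur(clusters, cfg$min_whisker_len)
}
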