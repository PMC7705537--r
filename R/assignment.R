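#' Optimal one-to-one assignment
#'
#' Minimum-total-cost assignment of rows to columns of a cost matrix
#' (shortest augmenting path / Jonker-Volgenant scheme, O(n^3)).
#' Rectangular matrices are padded internally; `Inf` entries are treated as
#' forbidden.
#'
#' @param cost numeric cost matrix (rows = agents, columns = tasks)
#' @return integer vector of length `nrow(cost)`: assigned column per row,
#'   `NA` for rows matched only to padding
#' @export
solve_assignment <- function(cost) {
  cost <- rbind(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  N <- max(n, m)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) (max(abs(finite)) + 1) * (N + 1) else 1
  C <- matrix(big, N, N)
  Cf <- cost; Cf[!is.finite(Cf)] <- big
  C[seq_len(n), seq_len(m)] <- Cf
  INF <- .Machine$double.xmax / 4
  u <- numeric(N)
  v <- numeric(N + 1)          # index j+1 <-> column j, column 0 virtual
  p <- integer(N + 1)          # row assigned to column j (0 = none)
  for (i in seq_len(N)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, N)
    used <- rep(FALSE, N + 1)
    way <- integer(N)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0
      for (j in seq_len(N)) {
        if (used[j + 1]) next
        cur <- C[i0, j] - u[i0] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:N) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  r2c <- rep(NA_integer_, N)
  for (j in seq_len(N)) if (p[j + 1] > 0) r2c[p[j + 1]] <- j
  out <- r2c[seq_len(n)]
  out[!is.na(out) & out > m] <- NA_integer_
  out
}
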