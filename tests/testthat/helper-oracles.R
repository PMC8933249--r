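# shared oracles and fixtures, all built in code at test time

# exhaustive cyclic-path enumeration over a node/edge profile graph
brute_force_cycle <- function(node, edge) {
  n <- nrow(node); K <- ncol(node)
  grids <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- Inf; bp <- NULL
  for (r in seq_len(nrow(grids))) {
    p <- as.integer(grids[r, ])
    cst <- sum(node[cbind(seq_len(n), p)])
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cst <- cst + edge[i, p[i], p[j]]
    }
    if (cst < best - 1e-12) { best <- cst; bp <- p }
  }
  list(cost = best, path = bp)
}

# mean absolute discrete curvature (inverse circumradius) of a closed polygon
mean_abs_curvature <- function(v) {
  n <- nrow(v)
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  prv <- rbind(v[n, , drop = FALSE], v[-n, , drop = FALSE])
  ab <- v - prv; bc <- nxt - v; ac <- nxt - prv
  cross <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  den <- sqrt(rowSums(ab^2)) * sqrt(rowSums(bc^2)) * sqrt(rowSums(ac^2))
  mean(2 * abs(cross) / pmax(den, 1e-9))
}

# spherical chi inclusion on a grid, 1-based center
sphere_chi <- function(grid, center, radius, chi_ppb) {
  a <- array(0, grid)
  for (k in seq_len(grid[3]))
    a[, , k] <- ifelse(outer((seq_len(grid[1]) - center[1])^2,
                             (seq_len(grid[2]) - center[2])^2, `+`) +
                         (k - center[3])^2 <= radius^2, chi_ppb, 0)
  a
}

circle_contour <- function(cx, cy, r, n = 120L, slice = 1L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(slice, cbind(cx + r * cos(th), cy + r * sin(th)))
}

# cached small cohort + template for the pipeline tests (built once per run)
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_fixture <- function() {
  if (!is.null(.pipeline_cache$fix)) return(.pipeline_cache$fix)
  best <- make_midbrain_phantom(seed = 0, warp = FALSE)
  train <- make_cohort(4, seed_offset = 0)
  be <- registration_backend(demons_iter = 15L, affine_maxit = 200L)
  bundle <- build_template(c(list(best), train), backend = be)
  .pipeline_cache$fix <- list(best = best, train = train, bundle = bundle,
                              backend = be)
  .pipeline_cache$fix
}

# 8-connected component count of a logical matrix (small masks only)
count_components8 <- function(m, conn = 8L) {
  m <- matrix(m != 0, nrow(m), ncol(m))
  lab <- matrix(0L, nrow(m), ncol(m))
  nc <- 0L
  for (s0 in which(m)) {
    if (lab[s0] != 0L) next
    nc <- nc + 1L
    stack <- s0
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !m[p]) next
      lab[p] <- nc
      i <- (p - 1L) %% nrow(m) + 1L
      j <- (p - 1L) %/% nrow(m) + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (conn == 4L && abs(di) + abs(dj) != 1L) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] && lab[ii, jj] == 0L)
          stack <- c(stack, (jj - 1L) * nrow(m) + ii)
      }
    }
  }
  nc
}
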