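#' Zhang-Suen skeletonization of a binary mask
#'
#' Iterative two-subpass thinning run to convergence. The result is a
#' single-pixel-wide, 8-connected centerline that preserves the connectivity
#' of the input; thinning is idempotent (thinning a centerline returns it
#' unchanged). Used to re-anchor the boundary-refinement profiles on the
#' structure's medial axis at each iteration.
#'
#' @param mask logical or 0/1 numeric matrix; must contain at least one
#'   foreground pixel.
#' @return logical matrix of the same size (the centerline), with class
#'   `centerline`.
#' @export
thin_mask <- function(mask) {
  m <- matrix(mask != 0, nrow(mask), ncol(mask))
  if (!any(m)) stop("thin_mask: empty mask", call. = FALSE)
  shift <- function(x, di, dj) {
    n <- nrow(x); p <- ncol(x)
    out <- matrix(FALSE, n, p)
    si <- seq_len(n) - di; sj <- seq_len(p) - dj
    ok_i <- si >= 1 & si <= n; ok_j <- sj >= 1 & sj <= p
    out[ok_i, ok_j] <- x[si[ok_i], sj[ok_j]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift(m, 0, 1); p3 <- shift(m, 1, 1); p4 <- shift(m, 1, 0)
      p5 <- shift(m, 1, -1); p6 <- shift(m, 0, -1); p7 <- shift(m, -1, -1)
      p8 <- shift(m, -1, 0); p9 <- shift(m, -1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  structure(m, class = c("centerline", "matrix", "array"))
}

#' @rdname thin_mask
#' @param cl a centerline (or any logical matrix).
#' @return `centerline_points()`: n x 2 matrix of 0-based pixel-center
#'   coordinates of the centerline pixels.
#' @export
centerline_points <- function(cl) {
  w <- which(unclass(cl) != 0, arr.ind = TRUE)
  cbind(w[, 1] - 1, w[, 2] - 1)
}
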