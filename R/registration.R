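#' Spatial transform between template and subject space
#'
#' An invertible mapping composed of an in-plane affine stage (rotation,
#' scale, shear, translation about a center), a through-plane translation,
#' and an optional dense in-plane displacement field defined on the template
#' grid. The forward direction maps template-space voxel coordinates to
#' subject-space coordinates (the pull-back used both to resample the
#' subject onto the template grid and to carry template boundaries into the
#' subject); the inverse is evaluated by fixed-point iteration.
#'
#' @param A2 2 x 2 in-plane linear part.
#' @param t2 in-plane translation (pixels).
#' @param tz through-plane translation (slices).
#' @param center in-plane center of rotation (0-based voxel coords).
#' @param ux,uy optional 3D arrays (template grid) of in-plane displacement.
#' @param dim_fixed dimensions of the template grid the transform lives on.
#' @return object of class `spatial_transform`.
#' @export
spatial_transform <- function(A2 = diag(2), t2 = c(0, 0), tz = 0,
                              center = c(0, 0), ux = NULL, uy = NULL,
                              dim_fixed = NULL) {
  structure(list(A2 = A2, t2 = t2, tz = tz, center = center,
                 ux = ux, uy = uy, dim_fixed = dim_fixed),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf(paste0("<spatial_transform> |t|=(%.2f, %.2f, %.2f) px, ",
                     "det A=%.3f, dense field: %s\n"),
              x$t2[1], x$t2[2], x$tz, det(x$A2),
              if (is.null(x$ux)) "none" else
                sprintf("max %.2f px", max(sqrt(x$ux^2 + x$uy^2)))))
  invisible(x)
}

#' Apply a spatial transform to points
#'
#' @param tf a [spatial_transform()].
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @param from `"template"` applies the forward map (template to subject);
#'   `"subject"` applies the inverse.
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(tf, pts, from = c("template", "subject")) {
  from <- match.arg(from)
  pts <- matrix(as.numeric(pts), ncol = 3)
  s <- tf$space_scale %||% 1
  if (s != 1) {
    tf2 <- tf; tf2$space_scale <- NULL
    q <- pts; q[, 1:2] <- q[, 1:2] / s
    out <- transform_points(tf2, q, from = from)
    out[, 1:2] <- out[, 1:2] * s
    return(out)
  }
  fwd <- function(p) {
    xy <- sweep(p[, 1:2, drop = FALSE], 2, tf$center)
    xy <- xy %*% t(tf$A2)
    xy <- sweep(xy, 2, tf$center + tf$t2, `+`)
    z <- p[, 3] + tf$tz
    if (!is.null(tf$ux)) {
      d <- dim(tf$ux)
      xy[, 1] <- xy[, 1] + cpp_interp3(as.numeric(tf$ux), as.integer(d),
                                       p[, 1], p[, 2], p[, 3])
      xy[, 2] <- xy[, 2] + cpp_interp3(as.numeric(tf$uy), as.integer(d),
                                       p[, 1], p[, 2], p[, 3])
    }
    cbind(xy, z)
  }
  if (from == "template") return(fwd(pts))
  # inverse by fixed-point iteration: find y with fwd(y) = p
  Ainv <- solve(tf$A2)
  y <- pts
  y[, 3] <- pts[, 3] - tf$tz
  xy <- sweep(pts[, 1:2, drop = FALSE], 2, tf$center + tf$t2)
  y[, 1:2] <- sweep(xy %*% t(Ainv), 2, tf$center, `+`)
  for (i in 1:15) {
    r <- fwd(y) - pts
    if (max(abs(r)) < 1e-4) break
    y[, 1:2] <- y[, 1:2] - r[, 1:2] %*% t(Ainv)
    y[, 3] <- y[, 3] - r[, 3]
  }
  y
}

#' Resample a subject volume onto the template grid
#'
#' `out[x] = moving[tf(x)]` for every voxel `x` of the template grid
#' (trilinear interpolation, edge-clamped).
#'
#' @param moving 3D array or [volume3d()] (subject space).
#' @param tf a [spatial_transform()].
#' @param dim_fixed dimensions of the output (template) grid; defaults to
#'   the transform's grid, else the moving image's.
#' @return 3D array.
#' @export
warp_volume <- function(moving, tf, dim_fixed = NULL) {
  a <- if (inherits(moving, "volume3d")) moving$data else moving
  d <- dim_fixed %||% tf$dim_fixed %||% dim(a)
  g <- fixed_grid(d)
  p <- transform_points(tf, g)
  array(cpp_interp3(as.numeric(a), as.integer(dim(a)), p[, 1], p[, 2], p[, 3]),
        d)
}

#' Re-express a transform on a grid scaled in-plane by a factor
#'
#' Conjugates the mapping with an in-plane scaling, so a transform estimated
#' on a coarser grid can be applied in finer-grid coordinates (e.g. fitted
#' at x2 zoom, applied at x4).
#'
#' @param tf a [spatial_transform()].
#' @param s in-plane scale factor between the new and the fitted grid.
#' @return a [spatial_transform()] operating in the scaled coordinates.
#' @export
scale_transform <- function(tf, s) {
  tf$space_scale <- (tf$space_scale %||% 1) * s
  tf
}

fixed_grid <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Reference registration backend
#'
#' Multi-resolution in-plane affine registration (sum-of-squared-differences
#' metric, Nelder-Mead) with a through-plane translation, optionally
#' followed by a diffusion-regularized demons refinement estimating a dense
#' in-plane displacement field. Deterministic for fixed inputs. Registration
#' numerics are deliberately pluggable: any object with the same `$run()`
#' contract can stand in.
#'
#' @param deformable fit the dense displacement stage (default `TRUE`).
#' @param demons_iter demons iterations (default 40).
#' @param demons_sigma Gaussian regularization sigma in pixels (default 2.5).
#' @param affine_maxit Nelder-Mead iteration budget per resolution level.
#' @return list of class `registration_backend` with capability flags and a
#'   `run(fixed, moving, slices, deformable)` function returning a
#'   [spatial_transform()].
#' @export
registration_backend <- function(deformable = TRUE, demons_iter = 40L,
                                 demons_sigma = 2.5, affine_maxit = 250L) {
  be <- list(rigid = TRUE, affine = TRUE, bspline = deformable,
             metric = "SSD", demons_iter = as.integer(demons_iter),
             demons_sigma = demons_sigma, affine_maxit = as.integer(affine_maxit))
  be$run <- function(fixed, moving, slices = NULL, deformable = be$bspline,
                     tz_search = 3L) {
    fa <- if (inherits(fixed, "volume3d")) fixed$data else fixed
    ma <- if (inherits(moving, "volume3d")) moving$data else moving
    tf <- register_affine(fa, ma, slices = slices, maxit = be$affine_maxit,
                          tz_search = tz_search)
    if (deformable)
      tf <- register_demons(fa, ma, tf, slices = slices,
                            iters = be$demons_iter, sigma = be$demons_sigma)
    tf
  }
  class(be) <- "registration_backend"
  be
}

# in-plane affine + z-shift by SSD, two resolution levels
register_affine <- function(fixed, moving, slices = NULL, maxit = 250L,
                            tz_search = 3L) {
  d <- dim(fixed)
  if (is.null(slices)) slices <- seq_len(d[3])
  ctr <- c((d[1] - 1) / 2, (d[2] - 1) / 2)
  dm <- as.integer(dim(moving))
  mnum <- as.numeric(moving)
  make_ssd <- function(step) {
    idx <- seq(1, d[1], by = step)
    jdx <- seq(1, d[2], by = step)
    g <- cbind(rep(idx - 1, times = length(jdx) * length(slices)),
               rep(rep(jdx - 1, each = length(idx)), times = length(slices)),
               rep(slices - 1, each = length(idx) * length(jdx)))
    f <- fixed[cbind(g[, 1] + 1, g[, 2] + 1, g[, 3] + 1)]
    function(par) {
      p <- transform_points(par_to_tf(par, ctr), g)
      w <- cpp_interp3(mnum, dm, p[, 1], p[, 2], p[, 3])
      mean((f - w)^2)
    }
  }
  # integer z-shift scan, then Nelder-Mead coarse -> fine
  s4 <- make_ssd(4L)
  p0 <- c(0, 0, 0, 0, 0, 0, 0)
  best <- Inf; bz <- 0
  for (z in -tz_search:tz_search) {
    v <- s4(c(0, 0, 0, 0, 0, 0, z))
    if (v < best) { best <- v; bz <- z }
  }
  p0[7] <- bz
  psc <- c(2, 2, 0.05, 0.02, 0.02, 0.02, 0.5)
  o1 <- stats::optim(p0, make_ssd(3L), method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-8,
                                    parscale = psc))
  o2 <- stats::optim(o1$par, make_ssd(2L), method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-9,
                                    parscale = psc))
  tf <- par_to_tf(o2$par, ctr)
  tf$dim_fixed <- d
  tf
}

par_to_tf <- function(par, center) {
  th <- par[3]
  S <- diag(exp(par[4:5]))
  Sh <- matrix(c(1, par[6], 0, 1), 2, 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  spatial_transform(A2 = R %*% Sh %*% S, t2 = par[1:2], tz = par[7],
                    center = center)
}

# Thirion-style demons on top of an affine initialization; in-plane field
register_demons <- function(fixed, moving, tf, slices = NULL, iters = 40L,
                            sigma = 2.5, max_step = 1.0) {
  d <- dim(fixed)
  if (is.null(slices)) slices <- seq_len(d[3])
  sc <- max(abs(fixed)) %||% 1
  if (sc == 0) sc <- 1
  f <- fixed / sc
  m <- moving / sc
  ux <- array(0, d); uy <- array(0, d)
  g <- fixed_grid(d)
  base <- transform_points(spatial_transform(tf$A2, tf$t2, tf$tz, tf$center),
                           g)
  for (it in seq_len(iters)) {
    px <- base[, 1] + as.numeric(ux)
    py <- base[, 2] + as.numeric(uy)
    w <- array(cpp_interp3(as.numeric(m), as.integer(d), px, py, base[, 3]), d)
    r <- f - w
    gx <- array(0, d); gy <- array(0, d)
    gx[2:(d[1] - 1), , ] <- (w[3:d[1], , ] - w[1:(d[1] - 2), , ]) / 2
    gy[, 2:(d[2] - 1), ] <- (w[, 3:d[2], ] - w[, 1:(d[2] - 2), ]) / 2
    den <- gx^2 + gy^2 + r^2
    den[den < 1e-8] <- Inf
    dux <- r * gx / den
    duy <- r * gy / den
    dux <- pmin(pmax(dux, -max_step), max_step)
    duy <- pmin(pmax(duy, -max_step), max_step)
    ux <- smooth_field(ux + dux, sigma)
    uy <- smooth_field(uy + duy, sigma)
  }
  spatial_transform(tf$A2, tf$t2, tf$tz, tf$center, ux = ux, uy = uy,
                    dim_fixed = d)
}

# Gaussian smoothing of a displacement component: separable in-plane
# convolution batched over all slices, plus a light 1-2-1 mix across slices
smooth_field <- function(u, sigma, slices = NULL) {
  d <- dim(u)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_ax1 <- function(a) {
    dd <- dim(a)
    n <- dd[1]
    ap <- a[c(rep(1, h), seq_len(n), rep(n, h)), , , drop = FALSE]
    out <- array(0, dd)
    for (t in 0:(2 * h))
      out <- out + k[t + 1] * ap[(1 + t):(n + t), , , drop = FALSE]
    out
  }
  u <- conv_ax1(u)
  u <- aperm(conv_ax1(aperm(u, c(2, 1, 3))), c(2, 1, 3))
  if (d[3] >= 3) {
    v <- u
    v[, , 2:(d[3] - 1)] <- 0.25 * u[, , 1:(d[3] - 2)] +
      0.5 * u[, , 2:(d[3] - 1)] + 0.25 * u[, , 3:d[3]]
    u <- v
  }
  u
}
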