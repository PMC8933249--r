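#' Two-intensity shape phantoms for boundary-refinement validation
#'
#' Generates the flat shapes used to validate the dynamic-programming
#' boundary refinement: a 35 x 40 px rectangle (true area exactly 1,400
#' pixels), a crescent ("moon", a disk minus an offset disk), a "cashew"
#' (union of two offset disks with lightly smoothed intensity), and a disk.
#' Noise is added so that the contrast-to-noise ratio
#' `(mean_in - mean_out) / sigma` equals `cnr`; `cnr = Inf` gives the
#' noise-free image.
#'
#' @param shape one of `"rectangle"`, `"moon"`, `"cashew"`, `"disk"`.
#' @param canvas canvas size in pixels (length 2).
#' @param inside,outside the two intensity levels.
#' @param cnr contrast-to-noise ratio (default 7, as in the validation
#'   figures); `Inf` for noise-free.
#' @param noise `"gaussian"` or `"rician"`.
#' @param seed RNG seed for the noise field (optional but recommended).
#' @param size shape scale: rectangle half-sides, disk radius, etc.;
#'   `NULL` uses the canonical defaults.
#' @return list with `image` (matrix), `truth` (logical matrix),
#'   `init_contour` (an enclosing starting [contour()] around the central
#'   area), and `spec` (the generating parameters).
#' @export
make_shape_phantom <- function(shape = c("rectangle", "moon", "cashew", "disk"),
                               canvas = c(100, 100), inside = 200,
                               outside = 100, cnr = 7,
                               noise = c("gaussian", "rician"), seed = NULL,
                               size = NULL) {
  shape <- match.arg(shape)
  noise <- match.arg(noise)
  if (cnr <= 0) stop("make_shape_phantom: cnr must be > 0", call. = FALSE)
  nx <- canvas[1]; ny <- canvas[2]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  X <- matrix(rep(0:(nx - 1), ny), nx, ny)
  Y <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  img <- matrix(outside, nx, ny)
  truth <- switch(shape,
    rectangle = {
      wh <- size %||% c(35, 40)   # 35 x 40 -> area exactly 1400 px
      lo <- round(c(cx, cy)) - floor((wh - 1) / 2)
      X >= lo[1] & X <= lo[1] + wh[1] - 1 & Y >= lo[2] & Y <= lo[2] + wh[2] - 1
    },
    disk = {
      r <- size %||% 20
      (X - cx)^2 + (Y - cy)^2 <= r^2
    },
    moon = {
      r <- size %||% 22
      (X - cx)^2 + (Y - cy)^2 <= r^2 &
        (X - cx - 0.45 * r)^2 + (Y - cy)^2 > (0.75 * r)^2
    },
    cashew = {
      r <- size %||% 14
      ((X - cx + 0.6 * r)^2 + (Y - cy - 0.35 * r)^2 <= r^2) |
        ((X - cx - 0.6 * r)^2 + (Y - cy + 0.35 * r)^2 <= r^2)
    })
  if (any(truth[c(1, nx), ]) || any(truth[, c(1, ny)]))
    stop("make_shape_phantom: shape too large for the canvas", call. = FALSE)
  img[truth] <- inside
  if (shape == "cashew") {
    # lightly smoothed intensity profile
    img <- smooth_field(array(img, c(nx, ny, 1)), sigma = 1)[, , 1]
  }
  if (is.finite(cnr)) {
    if (!is.null(seed)) set.seed(seed)
    sd <- (inside - outside) / cnr
    if (noise == "gaussian") {
      img <- img + matrix(stats::rnorm(nx * ny, 0, sd), nx, ny)
    } else {
      img <- sqrt((img + matrix(stats::rnorm(nx * ny, 0, sd), nx, ny))^2 +
                    matrix(stats::rnorm(nx * ny, 0, sd), nx, ny)^2)
    }
  }
  # starting region drawn around the central area: an ellipse hugging the
  # object a few pixels outside its edges, well within the search range
  w <- which(truth, arr.ind = TRUE)
  hx <- (max(w[, 1]) - min(w[, 1])) / 2
  hy <- (max(w[, 2]) - min(w[, 2])) / 2
  th <- seq(0, 2 * pi, length.out = 81)[-81]
  init <- contour(1L, cbind(cx + (hx + 3) * cos(th),
                            cy + (hy + 3) * sin(th)))
  list(image = img, truth = truth, init_contour = init,
       spec = list(shape = shape, canvas = canvas, inside = inside,
                   outside = outside, cnr = cnr, noise = noise, seed = seed))
}

#' Dipole-forward susceptibility phantom with wrapped phase
#'
#' Builds a piecewise-constant susceptibility distribution from spherical
#' inclusions, computes the induced field through the unit dipole response,
#' scales it to phase at the given echo time, and wraps to (-pi, pi].
#' Optionally adds a strong external (outside-mask) source so the
#' background-removal stage can be exercised.
#'
#' @param grid length-3 grid size.
#' @param spheres list of `list(center, radius, chi_ppb)` inclusions
#'   (centers in 1-based voxel units).
#' @param mask_radius radius of the spherical "brain" mask around the grid
#'   center.
#' @param external if `TRUE`, adds a susceptibility sphere outside the mask
#'   (an air-cavity-like background source).
#' @param config a [qsm_config()] supplying TE/B0 scaling.
#' @param noise_sd phase noise SD in radians (0 = noise-free).
#' @param seed RNG seed for the noise.
#' @return list with `phase` (wrapped, radians), `chi_truth` (ppb),
#'   `mask`, `field_ppb`.
#' @export
make_qsm_phantom <- function(grid = c(64, 64, 64), spheres = NULL,
                             mask_radius = NULL, external = FALSE,
                             config = qsm_config(), noise_sd = 0,
                             seed = NULL) {
  ctr <- (grid + 1) / 2
  if (is.null(spheres))
    spheres <- list(list(center = ctr, radius = 6, chi_ppb = 100))
  if (is.null(mask_radius)) mask_radius <- min(grid) / 2 - 10
  r2 <- array(0, grid)
  xg <- seq_len(grid[1]) - ctr[1]
  yg <- seq_len(grid[2]) - ctr[2]
  for (k in seq_len(grid[3]))
    r2[, , k] <- outer(xg^2, yg^2, `+`) + (k - ctr[3])^2
  mask <- r2 <= mask_radius^2
  chi <- array(0, grid)
  for (s in spheres) {
    rs <- array(0, grid)
    for (k in seq_len(grid[3]))
      rs[, , k] <- outer((seq_len(grid[1]) - s$center[1])^2,
                         (seq_len(grid[2]) - s$center[2])^2, `+`) +
        (k - s$center[3])^2
    chi[rs <= s$radius^2] <- s$chi_ppb
  }
  chi_all <- chi
  if (external) {
    zc <- ctr[3] + mask_radius + 12
    ext <- array(0, grid)
    for (k in seq_len(grid[3]))
      ext[, , k] <- outer(xg^2, yg^2, `+`) + (k - zc)^2
    chi_all[ext <= 3^2] <- 1e4
  }
  fld <- forward_field(chi_all)
  ph <- fld * phase_scale(config)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ph <- ph + array(stats::rnorm(prod(grid), 0, noise_sd), grid)
  }
  ph <- atan2(sin(ph), cos(ph))
  list(phase = volume3d(ph, meta = list(TE = config$TE_ms, B0 = config$B0)),
       chi_truth = chi, mask = mask, field_ppb = fld)
}

# closed ellipse polygon in 0-based coords
ellipse_poly <- function(cx, cy, a, b, angle = 0, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(cx + x0 * cos(angle) - y0 * sin(angle),
        cy + x0 * sin(angle) + y0 * cos(angle))
}

# crescent polygon: arc of radius r around (cx, cy), angular span, tapered
# half-thickness profile
crescent_poly <- function(cx, cy, r, th0, th1, w, n = 36L, mirror = 1) {
  t <- seq(th0, th1, length.out = n)
  wt <- w * (1 - 0.65 * (2 * (seq_len(n) - 1) / (n - 1) - 1)^2)
  px <- cx + mirror * (r + wt) * cos(t)
  py <- cy + (r + wt) * sin(t)
  qx <- cx + mirror * (r - rev(wt)) * cos(rev(t))
  qy <- cy + (r - rev(wt)) * sin(rev(t))
  cbind(c(px, qx), c(py, qy))
}

base_midbrain_geometry <- function(rn_slices = 3L) {
  # full-volume slice layout (64 slices, 2 mm): crop 23..38 anchors the RN
  # middle slice at crop slice 10
  rn_z <- if (rn_slices == 2L) 32:33 else 31:33
  geom <- list()
  for (h in c(-1, 1)) {
    hemi <- if (h < 0) "L" else "R"
    rc <- c(31.5 + h * 6.5, 29)
    # RN: ovoid over rn_slices
    sc_rn <- if (rn_slices == 2L) c(1, 0.8) else c(0.75, 1, 0.8)
    for (i in seq_along(rn_z))
      geom <- c(geom, list(list(label = "RN", hemisphere = hemi,
                                slice = rn_z[i],
                                poly = ellipse_poly(rc[1], rc[2],
                                                    4.2 * sc_rn[i],
                                                    4.7 * sc_rn[i],
                                                    angle = 0.3 * h))))
    # SN: crescent arcing lateral-anterior around the RN, slices 28..32
    sn_z <- 28:32
    sc_sn <- c(0.8, 0.95, 1, 1, 0.9)
    for (i in seq_along(sn_z))
      geom <- c(geom, list(list(label = "SN", hemisphere = hemi,
                                slice = sn_z[i],
                                poly = crescent_poly(rc[1], rc[2],
                                                     9 * sc_sn[i],
                                                     th0 = 0.2, th1 = 2.05,
                                                     w = 3.4 * sc_sn[i],
                                                     mirror = h))))
    # STN: small ovoid anterosuperior to the SN, 2 slices above the RN top
    stn_z <- max(rn_z) + 1:2
    for (i in 1:2)
      geom <- c(geom, list(list(label = "STN", hemisphere = hemi,
                                slice = stn_z[i],
                                poly = ellipse_poly(31.5 + h * 11, 35.5,
                                                    3 * c(1, 0.85)[i],
                                                    4 * c(1, 0.85)[i],
                                                    angle = -0.5 * h))))
    # NM blob: covers the anterior SN arm plus the medial VTA territory
    nm_z <- 28:31
    sc_nm <- c(0.85, 1, 1, 0.9)
    for (i in seq_along(nm_z))
      geom <- c(geom, list(list(label = "NM", hemisphere = hemi,
                                slice = nm_z[i],
                                poly = ellipse_poly(31.5 + h * 6.8, 36.8,
                                                    4.6 * sc_nm[i],
                                                    5.6 * sc_nm[i],
                                                    angle = 0.35 * h))))
    # VTA: medial arm of the NM territory (the in-plane "Y" with its twin)
    for (i in seq_along(nm_z))
      geom <- c(geom, list(list(label = "VTA", hemisphere = hemi,
                                slice = nm_z[i],
                                poly = ellipse_poly(31.5 + h * 4.2, 37.6,
                                                    1.4, 2.2,
                                                    angle = -0.3 * h))))
    # BG: lateral background boxes on the NM slices
    bgx <- 31.5 + h * 22
    for (z in nm_z)
      geom <- c(geom, list(list(label = "BG", hemisphere = hemi, slice = z,
                                poly = cbind(c(bgx - 4, bgx + 4, bgx + 4,
                                               bgx - 4),
                                             c(10, 10, 18, 18)))))
  }
  geom
}

# smooth per-subject warp: affine jitter + in-plane sinusoid, z slice shift
sample_subject_warp <- function(seed, dz_range = 1L) {
  set.seed(seed)
  th <- stats::rnorm(1, 0, 2.5 * pi / 180)
  sx <- exp(stats::rnorm(2, 0, 0.025))
  sh <- stats::rnorm(1, 0, 0.02)
  t2 <- stats::rnorm(2, 0, 1.5)
  dz <- sample.int(2L * dz_range + 1L, 1L) - dz_range - 1L
  amp <- stats::rnorm(4, 0, 0.7)
  lam <- stats::runif(2, 25, 45)
  ph <- stats::runif(4, 0, 2 * pi)
  list(theta = th, scale = sx, shear = sh, t2 = t2, dz = dz,
       amp = amp, lambda = lam, phase = ph, center = c(31.5, 31.5))
}

apply_subject_warp <- function(pts, wp) {
  # pts: n x 2 in-plane coords; returns warped coords
  R <- matrix(c(cos(wp$theta), sin(wp$theta),
                -sin(wp$theta), cos(wp$theta)), 2, 2)
  Sh <- matrix(c(1, wp$shear, 0, 1), 2, 2)
  A <- R %*% Sh %*% diag(wp$scale)
  xy <- sweep(pts, 2, wp$center)
  xy <- xy %*% t(A)
  xy <- sweep(xy, 2, wp$center + wp$t2, `+`)
  xy[, 1] <- xy[, 1] + wp$amp[1] * sin(2 * pi * pts[, 2] / wp$lambda[1] +
                                         wp$phase[1]) +
    wp$amp[2] * cos(2 * pi * pts[, 1] / wp$lambda[2] + wp$phase[2])
  xy[, 2] <- xy[, 2] + wp$amp[3] * sin(2 * pi * pts[, 1] / wp$lambda[1] +
                                         wp$phase[3]) +
    wp$amp[4] * cos(2 * pi * pts[, 2] / wp$lambda[2] + wp$phase[4])
  xy
}

#' Synthetic midbrain phantom with paired NM and susceptibility volumes
#'
#' Emulates one subject of a midbrain imaging cohort on a 64 x 64 x 64 grid
#' (0.67 mm in-plane, 2 mm slices): a crescent iron-rich substantia nigra
#' (chi ~ N(125, 20) ppb over 5 slices), an ovoid red nucleus
#' (N(100, 15) ppb, 2 or 3 slices), a small subthalamic nucleus
#' (N(110, 15) ppb, 2 slices above the RN), a neuromelanin-bright blob at
#' 5-10% contrast over a 1,000 a.u. background covering the anterior SN and
#' the medial VTA territory, and lateral background boxes. Per-subject
#' anatomy is produced by a smooth random warp (small affine + sinusoidal
#' displacement + integer slice shift) applied to the base geometry; the
#' ground-truth contours are carried through the warp analytically.
#'
#' @param seed subject seed (drives both the warp and the noise).
#' @param warp apply the per-subject random warp (`FALSE` gives the base
#'   anatomy, used as the template best case).
#' @param contrast_pct NM contrast in percent over background; `NULL` draws
#'   uniformly from 6-9%.
#' @param rn_slices number of slices the red nucleus spans (2 or 3).
#' @param dz_range maximum magnitude of the random integer slice shift.
#' @param nigrosome_gap if `TRUE`, carves a low-susceptibility notch inside
#'   the SN (an N1-like gap) on its central slice.
#' @param nm_noise_sd,chi_noise_sd background noise levels (a.u., ppb).
#' @return list of class `midbrain_phantom`: `nm`, `chi` ([volume3d()]),
#'   `truth` (a [structure_set()] including NM, SN, RN, STN, VTA and BG),
#'   `warp` (the warp parameters or `NULL`), `contrast_pct`, `background`.
#' @export
make_midbrain_phantom <- function(seed = 1L, warp = TRUE, contrast_pct = NULL,
                                  rn_slices = 3L, dz_range = 1L,
                                  nigrosome_gap = FALSE,
                                  nm_noise_sd = 10, chi_noise_sd = 10) {
  stopifnot(rn_slices %in% c(2L, 3L))
  grid <- c(64L, 64L, 64L)
  geom <- base_midbrain_geometry(rn_slices)
  wp <- NULL
  if (warp) {
    wp <- sample_subject_warp(seed, dz_range)
    geom <- lapply(geom, function(g) {
      g$poly <- apply_subject_warp(g$poly, wp)
      g$slice <- g$slice + wp$dz
      g
    })
  }
  set.seed(seed + 10000L)
  if (is.null(contrast_pct)) contrast_pct <- stats::runif(1, 6, 9)
  bg_level <- 1000
  truth <- structure_set(lapply(geom, function(g)
    contour(g$slice, g$poly, label = g$label, hemisphere = g$hemisphere)))
  nm <- array(bg_level, grid)
  chi <- array(0, grid)
  chi_means <- c(SN = 125, RN = 100, STN = 110)
  chi_sds <- c(SN = 20, RN = 15, STN = 15)
  for (g in geom) {
    m <- cpp_poly_mask(g$poly, grid[1], grid[2], 1e-7)
    npx <- sum(m)
    if (npx == 0) next
    sl <- g$slice
    if (g$label == "NM") {
      pl <- nm[, , sl]
      pl[m] <- bg_level * (1 + contrast_pct / 100)
      nm[, , sl] <- pl
    } else if (g$label %in% names(chi_means)) {
      pl <- chi[, , sl]
      pl[m] <- stats::rnorm(npx, chi_means[g$label], chi_sds[g$label])
      chi[, , sl] <- pl
    }
  }
  if (nigrosome_gap) {
    for (h in c(-1, 1)) {
      gp <- ellipse_poly(31.5 + h * 8.8, 33.5, 1.6, 2.2)
      if (warp) gp <- apply_subject_warp(gp, wp)
      sl <- 30 + (wp$dz %||% 0)
      m <- cpp_poly_mask(gp, grid[1], grid[2], 1e-7)
      pl <- chi[, , sl]; pl[m] <- stats::rnorm(sum(m), 20, 10)
      chi[, , sl] <- pl
    }
  }
  nm <- nm + array(stats::rnorm(prod(grid), 0, nm_noise_sd), grid)
  chi <- chi + array(stats::rnorm(prod(grid), 0, chi_noise_sd), grid)
  structure(list(nm = volume3d(nm, spacing = c(0.67, 0.67, 2),
                               meta = list(TE = 7.5, units = "a.u.")),
                 chi = volume3d(chi, spacing = c(0.67, 0.67, 2),
                                meta = list(TE = 15, units = "ppb")),
                 truth = truth, warp = wp, contrast_pct = contrast_pct,
                 background = bg_level, rn_slices = rn_slices),
            class = "midbrain_phantom")
}

#' Generate a synthetic midbrain cohort
#'
#' @param n number of subjects.
#' @param seed_offset added to 1..n to give per-subject seeds.
#' @param ... passed to [make_midbrain_phantom()].
#' @return list of `midbrain_phantom` objects.
#' @export
make_cohort <- function(n, seed_offset = 0L, ...) {
  lapply(seq_len(n), function(i)
    make_midbrain_phantom(seed = i + seed_offset, ...))
}
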