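#' QSM reconstruction configuration
#'
#' Parameters of the susceptibility-mapping chain: SHARP background-field
#' removal (truncated deconvolution threshold 0.05, spherical kernel radius
#' 6 voxels), truncated k-space division (threshold 0.1) and its iterative
#' refinement (threshold 0.1, 4 iterations). Scaling constants for the
#' radian-to-ppb conversion (gyromagnetic ratio, field strength, echo time)
#' travel with the config.
#'
#' @param sharp_tsvd_threshold truncation threshold for the SHARP
#'   deconvolution, in (0, 1).
#' @param sharp_kernel_radius_voxels radius of the spherical-mean kernel in
#'   voxels, >= 1.
#' @param tkd_threshold truncation threshold on the dipole kernel for TKD.
#' @param iter_threshold image-domain threshold (fraction of the current
#'   map's maximum) used by the iterative refinement.
#' @param n_iterations number of refinement iterations (default 4).
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param B0 main field strength, Tesla.
#' @param TE_ms echo time in ms used for the phase-to-susceptibility scaling.
#' @return list of class `qsm_config`.
#' @export
qsm_config <- function(sharp_tsvd_threshold = 0.05,
                       sharp_kernel_radius_voxels = 6,
                       tkd_threshold = 0.1,
                       iter_threshold = 0.1,
                       n_iterations = 4L,
                       gamma = 2.675e8, B0 = 3, TE_ms = 15) {
  stopifnot(sharp_tsvd_threshold > 0, sharp_tsvd_threshold < 1,
            sharp_kernel_radius_voxels >= 1,
            tkd_threshold > 0, tkd_threshold < 1,
            iter_threshold > 0, iter_threshold < 1)
  structure(list(sharp_tsvd_threshold = sharp_tsvd_threshold,
                 sharp_kernel_radius_voxels = sharp_kernel_radius_voxels,
                 tkd_threshold = tkd_threshold,
                 iter_threshold = iter_threshold,
                 n_iterations = as.integer(n_iterations),
                 gamma = gamma, B0 = B0, TE_ms = TE_ms),
            class = "qsm_config")
}

# ppb susceptibility -> radians of accumulated phase at TE
phase_scale <- function(config) config$gamma * config$B0 *
  (config$TE_ms / 1000) * 1e-9

fft_freqs <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Unit dipole response in k-space
#'
#' `D(k) = 1/3 - k_z'^2 / |k|^2`, with `k_z'` the k-component along the main
#' field direction and `D(0) = 0`. This kernel maps a susceptibility
#' distribution to the field perturbation it induces (both as fractions of
#' B0), and is the operator TKD inverts.
#'
#' @param grid_shape length-3 integer grid size (>= 8 per axis).
#' @param spacing voxel spacing (mm); anisotropic spacing skews the k grid.
#' @param B0_dir unit vector of the main field direction.
#' @return 3D array of kernel values in FFT layout (DC component first).
#' @export
dipole_kernel <- function(grid_shape, spacing = c(1, 1, 1),
                          B0_dir = c(0, 0, 1)) {
  if (sqrt(sum(B0_dir^2)) < 1e-12)
    stop("dipole_kernel: B0_dir must be a non-zero vector", call. = FALSE)
  if (any(grid_shape < 8))
    stop("dipole_kernel: grid must be at least 8 voxels per axis", call. = FALSE)
  b <- B0_dir / sqrt(sum(B0_dir^2))
  kx <- fft_freqs(grid_shape[1], spacing[1])
  ky <- fft_freqs(grid_shape[2], spacing[2])
  kz <- fft_freqs(grid_shape[3], spacing[3])
  KX <- array(kx, grid_shape)
  KY <- array(rep(ky, each = grid_shape[1]), grid_shape)
  KZ <- array(rep(kz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b[1] + KY * b[2] + KZ * b[3]
  D <- 1 / 3 - kb^2 / k2
  D[1, 1, 1] <- 0
  D
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the field perturbation (same units as `chi`) induced by a
#' susceptibility distribution via `IFFT(D(k) * FFT(chi))`.
#'
#' @param chi 3D array or [volume3d()] of susceptibility (e.g. ppb).
#' @param spacing,B0_dir passed to [dipole_kernel()].
#' @return 3D array of the induced field, in units of `chi` (fraction of B0
#'   if `chi` is a dimensionless fraction; ppb if `chi` is in ppb).
#' @export
forward_field <- function(chi, spacing = c(1, 1, 1), B0_dir = c(0, 0, 1)) {
  a <- if (inherits(chi, "volume3d")) chi$data else chi
  D <- dipole_kernel(dim(a), spacing, B0_dir)
  Re(stats::fft(D * stats::fft(a), inverse = TRUE)) / length(a)
}

#' Quality-guided phase unwrapping
#'
#' Best-path style region growing: voxels are committed in decreasing order
#' of a local phase-quality measure (negated sum of squared wrapped second
#' differences), each congruently unwrapped (`output = input + 2*pi*k`)
#' against the committed neighbour that reached it first. Voxels outside the
#' mask are returned untouched.
#'
#' @param phase 3D array or [volume3d()] of wrapped phase in radians,
#'   values in (-pi, pi].
#' @param mask logical array of voxels to unwrap; must be non-empty.
#' @return array (or volume, matching the input) of unwrapped phase.
#' @export
unwrap_phase <- function(phase, mask) {
  vol <- inherits(phase, "volume3d")
  a <- if (vol) phase$data else phase
  m <- array(as.logical(mask), dim(a))
  if (!any(m)) stop("unwrap_phase: empty mask", call. = FALSE)
  wrap <- function(x) atan2(sin(x), cos(x))
  q <- array(0, dim(a))
  for (ax in 1:3) {
    n <- dim(a)[ax]
    if (n < 3) next
    d <- wrap(take_ax(a, ax, 2:n) - take_ax(a, ax, 1:(n - 1)))
    sd2 <- wrap(take_ax(d, ax, 2:(n - 1)) - take_ax(d, ax, 1:(n - 2)))
    q <- q - insert_ax(sd2^2, dim(a), ax, 2:(n - 1))
  }
  out <- cpp_unwrap(as.numeric(a), as.integer(dim(a)), as.logical(m),
                    as.numeric(q))
  out <- array(out, dim(a))
  if (vol) volume3d(out, phase$spacing, phase$affine, phase$meta) else out
}

# helper: subset array along one axis
take_ax <- function(a, ax, k) {
  args <- rep(list(quote(expr = )), 3)
  args[[ax]] <- k
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# helper: place a smaller array into zeros along one axis
insert_ax <- function(small, d, ax, k) {
  out <- array(0, d)
  args <- rep(list(quote(expr = )), 3)
  args[[ax]] <- k
  do.call(`[<-`, c(list(out), args, list(small)))
}

# spherical kernel (radius in voxels) in FFT layout, normalized to sum 1
smv_kernel_fft <- function(grid_shape, radius) {
  cx <- fft_freqs(grid_shape[1]) * grid_shape[1]  # 0, 1, ..., -1 layout
  cy <- fft_freqs(grid_shape[2]) * grid_shape[2]
  cz <- fft_freqs(grid_shape[3]) * grid_shape[3]
  X <- array(cx, grid_shape)
  Y <- array(rep(cy, each = grid_shape[1]), grid_shape)
  Z <- array(rep(cz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  ker <- (X^2 + Y^2 + Z^2) <= radius^2 + 1e-9
  ker <- ker / sum(ker)
  stats::fft(ker)
}

#' SHARP background-field removal
#'
#' Spherical-mean-value filtering followed by truncated deconvolution:
#' harmonic (background-sourced) field components satisfy the mean-value
#' property and are annihilated by `(delta - rho)` filtering; the remaining
#' local field is recovered by dividing by `(1 - FFT(rho))` wherever that
#' factor exceeds `sharp_tsvd_threshold`. The output is valid on the mask
#' eroded by the kernel radius and zero elsewhere.
#'
#' @param unwrapped 3D array or [volume3d()] of unwrapped phase (radians).
#' @param mask logical brain mask.
#' @param config a [qsm_config()].
#' @return list: `field` (local field, radians, zero outside), `mask_eroded`.
#' @export
sharp_filter <- function(unwrapped, mask, config = qsm_config()) {
  a <- if (inherits(unwrapped, "volume3d")) unwrapped$data else unwrapped
  m <- array(as.logical(mask), dim(a))
  r <- config$sharp_kernel_radius_voxels
  Sk <- smv_kernel_fft(dim(a), r)
  # erode mask by the kernel radius: voxels whose whole sphere lies in-mask
  mconv <- Re(stats::fft(Sk * stats::fft(array(as.numeric(m), dim(a))),
                         inverse = TRUE)) / length(a)
  me <- mconv > 1 - 1e-6
  if (!any(me))
    stop("sharp_filter: mask too thin to erode by the SHARP kernel radius",
         call. = FALSE)
  am <- a * m
  hp <- am - Re(stats::fft(Sk * stats::fft(am), inverse = TRUE)) / length(a)
  hp <- hp * me
  H <- 1 - Sk
  Hm <- Mod(H)
  inv <- ifelse(Hm >= config$sharp_tsvd_threshold, 1 / H, 0)
  loc <- Re(stats::fft(inv * stats::fft(hp), inverse = TRUE)) / length(a)
  list(field = loc * me, mask_eroded = me)
}

#' Truncated k-space division (TKD) dipole inversion
#'
#' Divides the local-field spectrum by the dipole kernel where it is
#' well-conditioned (`|D| >= threshold`) and by `sign(D) * threshold`
#' elsewhere, then scales radians to ppb via `chi = phase / (gamma B0 TE)`.
#'
#' @param local_field 3D array or [volume3d()] of local field in radians at
#'   echo time `config$TE_ms`.
#' @param mask logical mask; output is zeroed outside.
#' @param config a [qsm_config()].
#' @param B0_dir main field direction.
#' @param spacing voxel spacing.
#' @return a [volume3d()] in ppb with `meta$units = "ppb"` and the mask in
#'   `meta$mask`.
#' @export
tkd_invert <- function(local_field, mask = NULL, config = qsm_config(),
                       B0_dir = c(0, 0, 1), spacing = c(1, 1, 1)) {
  a <- if (inherits(local_field, "volume3d")) local_field$data else local_field
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  m <- array(as.logical(mask), dim(a))
  D <- dipole_kernel(dim(a), spacing, B0_dir)
  t <- config$tkd_threshold
  Dsign <- ifelse(D >= 0, 1, -1)
  Dinv <- ifelse(abs(D) >= t, 1 / D, Dsign / t)
  Dinv[1, 1, 1] <- 0
  chik <- Dinv * stats::fft(a)
  chi <- Re(stats::fft(chik, inverse = TRUE)) / length(a)
  chi <- chi / phase_scale(config) * m
  volume3d(chi, spacing = spacing,
           meta = list(units = "ppb", mask = m, TE = config$TE_ms,
                       B0 = config$B0))
}

#' Iterative TKD with k-space cone replacement
#'
#' Starts from the plain TKD solution and, for `n_iterations` rounds,
#' re-estimates the k-space data inside the ill-conditioned cone
#' (`|D| < iter_threshold`) from the forward model of the current map
#' thresholded (in the image domain) at `iter_threshold` times its maximum,
#' keeping the well-conditioned k-space fixed. This suppresses streaking
#' while preserving the measured spectrum.
#'
#' @inheritParams tkd_invert
#' @return a [volume3d()] in ppb.
#' @export
iterative_tkd <- function(local_field, mask = NULL, config = qsm_config(),
                          B0_dir = c(0, 0, 1), spacing = c(1, 1, 1)) {
  if (config$n_iterations < 1)
    stop("iterative_tkd: n_iterations must be >= 1", call. = FALSE)
  a <- if (inherits(local_field, "volume3d")) local_field$data else local_field
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  m <- array(as.logical(mask), dim(a))
  D <- dipole_kernel(dim(a), spacing, B0_dir)
  t <- config$tkd_threshold
  ti <- config$iter_threshold
  well <- abs(D) >= ti
  Dsign <- ifelse(D >= 0, 1, -1)
  Dinv <- ifelse(abs(D) >= t, 1 / D, Dsign / t)
  Dinv[1, 1, 1] <- 0
  Fk <- stats::fft(a)
  chik_meas <- Dinv * Fk
  chi <- Re(stats::fft(chik_meas, inverse = TRUE)) / length(a)
  for (it in seq_len(config$n_iterations)) {
    mx <- max(abs(chi))
    if (mx <= 0) break
    chi_t <- chi * (abs(chi) >= ti * mx)
    Xk <- stats::fft(chi_t)
    Xk[well] <- chik_meas[well]
    chi <- Re(stats::fft(Xk, inverse = TRUE)) / length(a)
  }
  chi <- chi / phase_scale(config) * m
  volume3d(chi, spacing = spacing,
           meta = list(units = "ppb", mask = m, TE = config$TE_ms,
                       B0 = config$B0))
}

#' Full QSM reconstruction chain
#'
#' Unwraps the phase, removes background fields with SHARP, and inverts the
#' local field with iterative TKD. The brain mask is an input (skull
#' stripping is outside the scope of this package).
#'
#' @param phase wrapped phase, 3D array or [volume3d()] (radians).
#' @param mask logical brain mask.
#' @param config a [qsm_config()].
#' @param B0_dir,spacing geometry of the acquisition.
#' @param verbose print per-stage residual norms.
#' @return list with `chi` (the susceptibility [volume3d()], ppb),
#'   `local_field`, `unwrapped`, `mask_eroded`.
#' @export
qsm_reconstruct <- function(phase, mask, config = qsm_config(),
                            B0_dir = c(0, 0, 1), spacing = c(1, 1, 1),
                            verbose = FALSE) {
  uw <- unwrap_phase(phase, mask)
  ua <- if (inherits(uw, "volume3d")) uw$data else uw
  if (verbose) message(sprintf("unwrap: RMS %.4g rad", sqrt(mean(ua[mask]^2))))
  sh <- sharp_filter(ua, mask, config)
  if (verbose) message(sprintf("sharp : RMS %.4g rad on eroded mask",
                               sqrt(mean(sh$field[sh$mask_eroded]^2))))
  chi <- iterative_tkd(sh$field, sh$mask_eroded, config,
                       B0_dir = B0_dir, spacing = spacing)
  if (verbose) message(sprintf("tkd   : chi range [%.3g, %.3g] ppb",
                               min(chi$data), max(chi$data)))
  list(chi = chi, local_field = sh$field, unwrapped = ua,
       mask_eroded = sh$mask_eroded)
}
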