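#' @useDynLib midbrainseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D scalar volume with voxel spacing and orientation
#'
#' The basic container shared by every stage of the pipeline: a 3D array of
#' scalar intensities (axis order x, y, slice), the voxel spacing in mm, an
#' optional 4x4 voxel-to-world affine, and free-form acquisition metadata
#' (echo time, field strength, units).
#'
#' @param data numeric 3D array, axis order (x, y, slice).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; strictly
#'   positive.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @param meta named list of acquisition metadata (e.g. `TE` in ms, `B0` in
#'   Tesla, `units`).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be three strictly positive numbers", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume3d: affine must be 4x4", call. = FALSE)
  structure(list(data = data, spacing = spacing, affine = affine, meta = meta),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume3d <- function(x) {
  if (inherits(x, "volume3d")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(volume3d(x))
  stop("expected a volume3d or 3D array", call. = FALSE)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti. `read_volume()` refuses non-3D images;
#' round-tripping through `write_volume()` preserves the voxel data exactly
#' and the spacing/affine to better than 1e-6.
#'
#' @param path file path to a NIfTI-1/2 image (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume3d()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header or file: ",
                                           conditionMessage(e), call. = FALSE))
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L && d[4] == 1L) { a <- a[, , , 1L, drop = TRUE]; d <- dim(a) }
  if (length(d) == 2L) { a <- array(a, c(d, 1L)); d <- dim(a) }  # single slice
  if (length(d) != 3L)
    stop(sprintf("read_volume: expected a 3D image, got %dD", length(d)),
         call. = FALSE)
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, max(0, 3 - length(sp))))[1:3]
  sp[!is.finite(sp) | sp <= 0] <- 1
  xf <- unclass(RNifti::xform(img))
  aff <- rbind(cbind(xf[1:3, 1:3], xf[1:3, 4]), c(0, 0, 0, 1))
  if (all(abs(aff[1:3, 1:3]) < 1e-12)) aff <- diag(c(sp, 1))
  volume3d(array(as.numeric(a), d), spacing = sp, affine = aff)
}

#' @param vol a [volume3d()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  img <- RNifti::asNifti(structure(vol$data, pixdim = vol$spacing))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' In-plane zoom and through-plane slice interpolation
#'
#' `zoom_inplane()` resamples each slice on a grid refined by `factor` using
#' separable cubic-spline interpolation; `interp_slices()` linearly
#' interpolates in the slice-select direction to a finer slice spacing.
#' Both preserve the physical extent of the volume (pixel centers resampled
#' at `(k + 0.5)/m - 0.5` of the source grid) and, for smooth inputs, the
#' mean intensity to well within 1%.
#'
#' @param vol a [volume3d()] (or 3D array).
#' @param factor in-plane zoom factor, >= 1 (4 in the standard pipeline).
#' @return A [volume3d()] on the refined grid.
#' @export
zoom_inplane <- function(vol, factor) {
  vol <- as_volume3d(vol)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("zoom_inplane: factor must be a single number >= 1", call. = FALSE)
  if (factor == 1) return(vol)
  d <- dim(vol$data)
  nx2 <- as.integer(round(d[1] * factor))
  ny2 <- as.integer(round(d[2] * factor))
  xo <- (seq_len(nx2) - 0.5) / factor - 0.5   # 0-based source coords
  yo <- (seq_len(ny2) - 0.5) / factor - 0.5
  out <- array(0, c(nx2, ny2, d[3]))
  for (k in seq_len(d[3])) {
    sl <- vol$data[, , k]
    tmp <- matrix(0, nx2, d[2])
    for (j in seq_len(d[2]))
      tmp[, j] <- spline_sample(sl[, j], xo)
    sl2 <- matrix(0, nx2, ny2)
    for (i in seq_len(nx2))
      sl2[i, ] <- spline_sample(tmp[i, ], yo)
    out[, , k] <- sl2
  }
  volume3d(out, spacing = c(vol$spacing[1:2] / factor, vol$spacing[3]),
           meta = vol$meta)
}

# natural cubic spline sample of a vector at 0-based positions (clamped)
spline_sample <- function(v, at) {
  n <- length(v)
  at <- pmin(pmax(at, 0), n - 1)
  if (n < 4) return(stats::approx(x = 0:(n - 1), y = v, xout = at, rule = 2)$y)
  stats::spline(x = 0:(n - 1), y = v, xout = at, method = "natural")$y
}

#' @param target_dz target slice spacing in mm; must divide the source slice
#'   spacing to within 1e-6 (e.g. 2 mm -> 0.167 mm is a factor of 12).
#' @rdname zoom_inplane
#' @export
interp_slices <- function(vol, target_dz) {
  vol <- as_volume3d(vol)
  dz <- vol$spacing[3]
  m <- dz / target_dz
  if (abs(m - round(m)) > 1e-6 * m)
    stop("interp_slices: target_dz must divide the source slice spacing",
         call. = FALSE)
  m <- as.integer(round(m))
  if (m == 1L) return(vol)
  d <- dim(vol$data)
  nz2 <- d[3] * m
  zo <- (seq_len(nz2) - 0.5) / m - 0.5
  zo <- pmin(pmax(zo, 0), d[3] - 1)
  z0 <- pmin(floor(zo), d[3] - 2)
  fz <- zo - z0
  out <- array(0, c(d[1], d[2], nz2))
  for (k in seq_len(nz2)) {
    out[, , k] <- vol$data[, , z0[k] + 1] * (1 - fz[k]) +
      vol$data[, , z0[k] + 2] * fz[k]
  }
  volume3d(out, spacing = c(vol$spacing[1:2], dz / m), meta = vol$meta)
}

#' Trilinear sampling at continuous voxel coordinates
#'
#' Samples a volume at arbitrary continuous positions in the 0-based
#' pixel-center coordinate frame, clamping at the edges.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param pts n x 3 matrix of (x, y, z) coordinates, 0-based.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, pts) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_interp3(as.numeric(a), as.integer(dim(a)),
              pts[, 1], pts[, 2], pts[, 3])
}
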