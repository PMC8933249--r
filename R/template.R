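#' Template bundle for automatic midbrain segmentation
#'
#' Bundles everything the fully automatic segmentation needs: the averaged
#' NM and QSM template volumes on the zoomed midbrain crop (x4 in-plane, 16
#' slices), the finalized template boundaries and background ROIs indexed on
#' the 0.167 mm isotropic 192-slice grid, the per-contrast slice windows,
#' the full-brain reference volume the global registration targets, and the
#' red nucleus slice anchoring information.
#'
#' @param nm_zoom,qsm_zoom [volume3d()] templates on the zoomed crop grid.
#' @param boundaries [structure_set()] of NM/SN/RN/STN/VTA contours; slice
#'   indices on the 192-slice isotropic grid, vertices on the zoomed
#'   in-plane grid.
#' @param bg_rois [structure_set()] of BG contours, same coordinates.
#' @param windows list with `NM` and `QSM` slice ranges (192-grid) outside
#'   which boundaries are not mapped.
#' @param global_ref full-brain reference [volume3d()] (low resolution).
#' @param ref_rn integer slices of the red nucleus in `global_ref`.
#' @param crop_start first slice of the reference midbrain crop.
#' @param zoom in-plane zoom factor (4).
#' @param n_subjects_averaged number of subjects averaged into the templates.
#' @return object of class `template_bundle`.
#' @export
template_bundle <- function(nm_zoom, qsm_zoom, boundaries, bg_rois, windows,
                            global_ref, ref_rn, crop_start, zoom = 4L,
                            n_subjects_averaged = 1L) {
  structure(list(nm_zoom = nm_zoom, qsm_zoom = qsm_zoom,
                 boundaries = boundaries, bg_rois = bg_rois,
                 windows = windows, global_ref = global_ref,
                 ref_rn = as.integer(ref_rn),
                 crop_start = as.integer(crop_start), zoom = as.integer(zoom),
                 n_subjects_averaged = as.integer(n_subjects_averaged)),
            class = "template_bundle")
}

#' @export
print.template_bundle <- function(x, ...) {
  cat(sprintf(paste0("<template_bundle> %d-subject average, zoom x%d, ",
                     "%d boundary contours\n"),
              x$n_subjects_averaged, x$zoom, length(x$boundaries$contours)))
  invisible(x)
}

n_crop_slices <- 16L
z_interp_factor <- 12L

crop_to_z192 <- function(s) z_interp_factor * (s - 1L) + z_interp_factor %/% 2L
z192_to_crop <- function(z) (as.integer(z) - 1L) %/% z_interp_factor + 1L

#' Materialize a template volume at isotropic resolution
#'
#' Interpolates the stored 16-slice zoomed template in the slice-select
#' direction to the isotropic grid the boundaries are drawn on (192 slices
#' at 0.167 mm for the standard 2 mm acquisition).
#'
#' @param bundle a [template_bundle()].
#' @param what `"nm"` or `"qsm"`.
#' @return a [volume3d()] with 192 slices.
#' @export
template_isotropic <- function(bundle, what = c("nm", "qsm")) {
  what <- match.arg(what)
  v <- if (what == "nm") bundle$nm_zoom else bundle$qsm_zoom
  interp_slices(v, v$spacing[3] / z_interp_factor)
}

# downsample in-plane by 2 (2x2 block mean), used for the coarse local fit
downsample2 <- function(a) {
  d <- dim(a)
  n1 <- d[1] %/% 2L; n2 <- d[2] %/% 2L
  a <- a[seq_len(2 * n1), seq_len(2 * n2), , drop = FALSE]
  (a[seq(1, 2 * n1, 2), seq(1, 2 * n2, 2), , drop = FALSE] +
     a[seq(2, 2 * n1, 2), seq(1, 2 * n2, 2), , drop = FALSE] +
     a[seq(1, 2 * n1, 2), seq(2, 2 * n2, 2), , drop = FALSE] +
     a[seq(2, 2 * n1, 2), seq(2, 2 * n2, 2), , drop = FALSE]) / 4
}

crop_and_zoom <- function(vol, crop_start, zoom = 4L) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  sp <- if (inherits(vol, "volume3d")) vol$spacing else c(1, 1, 1)
  sl <- crop_start:(crop_start + n_crop_slices - 1L)
  zoom_inplane(volume3d(a[, , sl, drop = FALSE],
                        spacing = sp,
                        meta = list(crop_start = crop_start)), zoom)
}

#' Global mapping of a subject to the template reference
#'
#' Fits the full cascade (in-plane rigid/affine with through-plane
#' translation, then a dense deformable refinement) between the full-brain
#' reference and the subject over the central 50 slices. The same transform
#' applies to the co-registered susceptibility volume.
#'
#' @param subject_nm subject NM magnitude [volume3d()] (full brain, low
#'   resolution).
#' @param bundle a [template_bundle()].
#' @param backend a [registration_backend()].
#' @return a [spatial_transform()] (reference grid -> subject).
#' @export
global_map <- function(subject_nm, bundle, backend = registration_backend()) {
  ref <- bundle$global_ref$data
  nz <- dim(ref)[3]
  n50 <- min(50L, nz)
  lo <- max(1L, (nz - n50) %/% 2L + 1L)
  slices <- lo:(lo + n50 - 1L)
  sub <- if (inherits(subject_nm, "volume3d")) subject_nm$data else subject_nm
  tf <- backend$run(ref, sub, slices = slices)
  quality <- mean((ref[, , slices] - warp_volume(sub, tf, dim(ref))[, , slices])^2)
  base <- mean((ref[, , slices] - sub[, , slices])^2)
  if (!is.finite(quality) || quality > base)
    stop("global_map: registration diverged (SSD worsened)", call. = FALSE)
  tf
}

#' Locate the 16-slice midbrain crop by red nucleus anchoring
#'
#' Transforms the reference red nucleus slice span into the subject and
#' anchors the crop so the red nucleus lands on crop slice 10: if the
#' mapped RN occupies two slices the lower one becomes slice 10, if three
#' the middle one.
#'
#' @param subject_vol subject volume (for bounds checking).
#' @param tf_global transform from [global_map()].
#' @param bundle a [template_bundle()].
#' @return list with `anchor` (subject slice made crop slice 10),
#'   `crop_start`, `slices` (the 16 crop slices), `rn_slices` (the mapped
#'   RN slices).
#' @export
locate_crop <- function(subject_vol, tf_global, bundle) {
  a <- if (inherits(subject_vol, "volume3d")) subject_vol$data else subject_vol
  nz <- dim(a)[3]
  zr <- range(bundle$ref_rn)
  ctr <- c((dim(a)[1] - 1) / 2, (dim(a)[2] - 1) / 2)
  p <- transform_points(tf_global,
                        cbind(ctr[1], ctr[2], c(zr[1], zr[2]) - 1))
  zs <- sort(p[, 3]) + 1
  S <- seq.int(round(zs[1]), round(zs[2]))
  anchor <- if (length(S) <= 1L) S[1]
            else if (length(S) == 2L) S[1]              # lower of two
            else S[ceiling(length(S) / 2)]              # middle of three
  crop_start <- anchor - 9L
  if (crop_start < 1L || crop_start + n_crop_slices - 1L > nz)
    stop(sprintf(paste0("locate_crop: red nucleus anchor at slice %d leaves ",
                        "no room for a 16-slice crop (volume has %d slices)"),
                 anchor, nz), call. = FALSE)
  list(anchor = as.integer(anchor), crop_start = as.integer(crop_start),
       slices = as.integer(crop_start:(crop_start + n_crop_slices - 1L)),
       rn_slices = as.integer(S))
}

#' Local deformable mapping of the zoomed midbrain crop to the template
#'
#' Registers the subject's x4-zoomed 16-slice midbrain block to the zoomed
#' template crop. The numerics run at half the zoom (x2) for speed and the
#' fitted transform is re-expressed in full-zoom coordinates.
#'
#' @param subject_zoom subject zoomed crop [volume3d()] (from the crop
#'   located by [locate_crop()]).
#' @param bundle a [template_bundle()].
#' @param backend a [registration_backend()].
#' @return a [spatial_transform()] (template zoomed crop -> subject zoomed
#'   crop).
#' @export
local_map <- function(subject_zoom, bundle,
                      backend = registration_backend()) {
  fa <- downsample2(bundle$nm_zoom$data)
  ma <- downsample2(if (inherits(subject_zoom, "volume3d")) subject_zoom$data
                    else subject_zoom)
  tf <- backend$run(fa, ma, slices = seq_len(dim(fa)[3]), tz_search = 0L)
  scale_transform(tf, 2)
}

#' Map template boundaries into subject space
#'
#' Carries every template contour through the local transform into the
#' subject's zoomed crop, then down to original resolution and to the
#' subject's full-volume slice numbering. Contours are re-closed and
#' resampled to uniform arc length; structures are only mapped within their
#' contrast's slice window.
#'
#' @param bundle a [template_bundle()].
#' @param tf_local transform from [local_map()].
#' @param crop_start first subject slice of the crop (from [locate_crop()]).
#' @param which_sets map `"boundaries"`, `"bg"` or both (default both).
#' @return a [structure_set()] in subject-original coordinates, with
#'   attribute `zoom_vertices`: a parallel list of vertices in zoomed-crop
#'   coordinates plus crop slice, used by the refinement stage.
#' @export
map_boundaries_to_subject <- function(bundle, tf_local, crop_start,
                                      which_sets = c("boundaries", "bg")) {
  cts <- list()
  if ("boundaries" %in% which_sets) cts <- c(cts, bundle$boundaries$contours)
  if ("bg" %in% which_sets) cts <- c(cts, bundle$bg_rois$contours)
  out <- list()
  zoomv <- list()
  for (ct in cts) {
    win <- bundle$windows[[if (ct$label %in% c("NM", "VTA", "BG")) "NM"
                           else "QSM"]]
    if (!is.null(win) && (ct$slice < win[1] || ct$slice > win[2])) next
    s <- z192_to_crop(ct$slice)
    v <- resample_closed(ct$vertices, max(48L, nrow(ct$vertices)))
    p <- transform_points(tf_local, cbind(v, s - 1))
    s_sub <- round(stats::median(p[, 3])) + 1L
    if (s_sub < 1L || s_sub > n_crop_slices) next
    full_slice <- crop_start + s_sub - 1L
    newct <- contour(full_slice, p[, 1:2] / bundle$zoom,
                     label = ct$label, hemisphere = ct$hemisphere)
    out <- c(out, list(newct))
    zoomv <- c(zoomv, list(list(vertices = p[, 1:2], crop_slice = s_sub,
                                label = ct$label,
                                hemisphere = ct$hemisphere)))
  }
  res <- structure_set(out)
  attr(res, "zoom_vertices") <- zoomv
  res
}

#' Build a template bundle from a cohort
#'
#' The first subject is the designated best case and defines the reference
#' frame. Every other subject is globally mapped to it, cropped by the red
#' nucleus anchoring rule, zoomed x4 in-plane, locally deformed onto the
#' best case's zoomed crop, and the aligned NM/QSM blocks are voxelwise
#' averaged (the average acting as a probability map with sharper average
#' boundaries). Template boundaries start from the best case's reference
#' contours (ground truth for phantom cohorts, operator tracings otherwise)
#' and are finalized by the same dynamic-programming refinement used at
#' segmentation time.
#'
#' @param subjects list of subjects; each needs `nm`, `chi` ([volume3d()])
#'   and `truth` (a [structure_set()] with NM/SN/RN/STN/VTA/BG contours in
#'   its own full-volume space).
#' @param backend a [registration_backend()].
#' @param dpa_cfg a [dpa_config()] for the boundary finalization.
#' @param thr_cfg a [threshold_config()].
#' @param zoom in-plane zoom factor.
#' @param finalize_dpa run the refinement on the averaged template
#'   (default `TRUE`).
#' @return a [template_bundle()].
#' @export
build_template <- function(subjects, backend = registration_backend(),
                           dpa_cfg = dpa_config(), thr_cfg = threshold_config(),
                           zoom = 4L, finalize_dpa = TRUE) {
  if (length(subjects) < 1L) stop("build_template: no subjects", call. = FALSE)
  if (length(subjects) == 1L)
    warning("build_template: single subject; template equals that subject")
  best <- subjects[[1]]
  ref <- best$nm
  # crop the reference by its own red nucleus span (middle slice -> 10)
  rn_z <- sort(ss_slices(ss_filter(best$truth, label = "RN")))
  anchor <- if (length(rn_z) == 2L) rn_z[1] else rn_z[ceiling(length(rn_z) / 2)]
  crop_start <- anchor - 9L
  nz <- dim(ref$data)[3]
  if (crop_start < 1L || crop_start + n_crop_slices - 1L > nz)
    stop("build_template: reference red nucleus too close to the volume edge",
         call. = FALSE)
  acc_nm <- NULL; acc_qsm <- NULL
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (i == 1L) {
      nm_r <- s$nm$data; chi_r <- s$chi$data
    } else {
      tf_g <- backend$run(ref$data, s$nm$data,
                          slices = central_slices(nz, 50L))
      nm_r <- warp_volume(s$nm$data, tf_g, dim(ref$data))
      chi_r <- warp_volume(s$chi$data, tf_g, dim(ref$data))
    }
    nm_z <- crop_and_zoom(volume3d(nm_r, ref$spacing), crop_start, zoom)
    chi_z <- crop_and_zoom(volume3d(chi_r, ref$spacing), crop_start, zoom)
    if (i > 1L) {
      tf_l <- local_map(nm_z, template_bundle(
        nm_zoom = acc_first, qsm_zoom = acc_first, boundaries = structure_set(),
        bg_rois = structure_set(), windows = list(),
        global_ref = ref, ref_rn = rn_z, crop_start = crop_start,
        zoom = zoom), backend)
      nm_z$data <- warp_volume(nm_z$data, tf_l, dim(acc_first$data))
      chi_z$data <- warp_volume(chi_z$data, tf_l, dim(acc_first$data))
    } else {
      acc_first <- nm_z
    }
    acc_nm <- if (is.null(acc_nm)) nm_z$data else acc_nm + nm_z$data
    acc_qsm <- if (is.null(acc_qsm)) chi_z$data else acc_qsm + chi_z$data
  }
  nm_t <- volume3d(acc_nm / length(subjects),
                   spacing = acc_first$spacing)
  qsm_t <- volume3d(acc_qsm / length(subjects), spacing = acc_first$spacing)
  # boundaries from the best case, in zoomed-crop coordinates
  bnd <- list(); bg <- list()
  for (ct in best$truth$contours) {
    s <- ct$slice - crop_start + 1L
    if (s < 1L || s > n_crop_slices) next
    newct <- contour(crop_to_z192(s), ct$vertices * zoom, label = ct$label,
                     hemisphere = ct$hemisphere)
    if (ct$label == "BG") bg <- c(bg, list(newct))
    else bnd <- c(bnd, list(newct))
  }
  bnds <- structure_set(bnd)
  bgs <- structure_set(bg)
  bundle0 <- template_bundle(nm_t, qsm_t, bnds, bgs,
                             windows = boundary_windows(bnds),
                             global_ref = ref, ref_rn = rn_z,
                             crop_start = crop_start, zoom = zoom,
                             n_subjects_averaged = length(subjects))
  if (finalize_dpa) {
    bgst <- template_bg_stats(bundle0)
    flo <- nm_floor(bgst, thr_cfg)
    refined <- lapply(bundle0$boundaries$contours, function(ct) {
      s <- z192_to_crop(ct$slice)
      img <- if (ct$label %in% c("NM", "VTA")) nm_t$data[, , s]
             else qsm_t$data[, , s]
      if (ct$label == "VTA") return(ct)  # VTA is an anatomical prior, kept
      res <- tryCatch({
        if (ct$label == "NM") {
          dpa_refine(img, ct2crop(ct, s), dpa_cfg, intensity_floor = flo,
                     structure_id = ct$label)
        } else {
          qp <- qsm_prepare(img, ct2crop(ct, s), thr_cfg)
          dpa_refine(qp$map, ct2crop(ct, s), dpa_cfg,
                     intensity_floor = max(qp$threshold, 1e-6),
                     structure_id = ct$label)
        }
      }, error = function(e) NULL)
      if (is.null(res)) ct
      else contour(ct$slice, res$vertices, label = ct$label,
                   hemisphere = ct$hemisphere)
    })
    bundle0$boundaries <- structure_set(refined)
    bundle0$windows <- boundary_windows(bundle0$boundaries)
  }
  bundle0
}

ct2crop <- function(ct, s) contour(s, ct$vertices, label = ct$label,
                                   hemisphere = ct$hemisphere)

central_slices <- function(nz, n) {
  n <- min(n, nz)
  lo <- max(1L, (nz - n) %/% 2L + 1L)
  lo:(lo + n - 1L)
}

boundary_windows <- function(bnds) {
  z_nm <- vapply(bnds$contours[vapply(bnds$contours, function(ct)
    ct$label %in% c("NM", "VTA"), logical(1))], `[[`, integer(1), "slice")
  z_q <- vapply(bnds$contours[vapply(bnds$contours, function(ct)
    ct$label %in% c("SN", "RN", "STN"), logical(1))], `[[`, integer(1), "slice")
  list(NM = if (length(z_nm)) range(z_nm) else c(44L, 98L),
       QSM = if (length(z_q)) range(z_q) else c(44L, 126L))
}

template_bg_stats <- function(bundle) {
  cts <- lapply(bundle$bg_rois$contours, function(ct)
    ct2crop(ct, z192_to_crop(ct$slice)))
  background_stats(bundle$nm_zoom$data, structure_set(cts))
}

#' Fully automatic subject segmentation
#'
#' Runs the whole cascade with no manual input: global mapping to the
#' reference, red nucleus anchored crop, x4 in-plane zoom, local deformable
#' mapping to the template, inverse mapping of the template boundaries,
#' background-referenced NM flooring and negative-removal/Otsu preparation
#' of the susceptibility map, and per-structure dynamic-programming boundary
#' refinement. The red nucleus is refined first and its interior is blanked
#' when refining the substantia nigra (preventing leakage between the
#' abutting nuclei); the refined SN is blanked for the subthalamic nucleus.
#' The ventral tegmental area is carried as a mapped anatomical prior for
#' the downstream pars-compacta derivation.
#'
#' @param nm,chi subject NM magnitude and susceptibility [volume3d()]s
#'   (co-registered, full volume).
#' @param bundle a [template_bundle()].
#' @param backend a [registration_backend()].
#' @param dpa_cfg a [dpa_config()].
#' @param thr_cfg a [threshold_config()].
#' @param sd_ref optional cohort-calibrated background SD for the NM floor.
#' @return list of class `segmentation_result`: `structures` (refined
#'   [structure_set()], subject space), `mapped` (pre-refinement mapped
#'   boundaries), `background` ([background_stats()]), `errors` (named list
#'   of per-structure failures), `crop`, `tf_global`, `tf_local`.
#' @export
segment_subject <- function(nm, chi, bundle,
                            backend = registration_backend(),
                            dpa_cfg = dpa_config(),
                            thr_cfg = threshold_config(), sd_ref = NULL) {
  tf_g <- global_map(nm, bundle, backend)
  crop <- locate_crop(nm, tf_g, bundle)
  nm_z <- crop_and_zoom(nm, crop$crop_start, bundle$zoom)
  chi_z <- crop_and_zoom(chi, crop$crop_start, bundle$zoom)
  tf_l <- local_map(nm_z, bundle, backend)
  mapped <- map_boundaries_to_subject(bundle, tf_l, crop$crop_start)
  zoomv <- attr(mapped, "zoom_vertices")
  # background statistics from the mapped BG ROIs (zoomed crop space)
  bg_cts <- structure_set(lapply(
    Filter(function(z) z$label == "BG", zoomv),
    function(z) contour(z$crop_slice, z$vertices, label = "BG",
                        hemisphere = z$hemisphere)))
  bgst <- background_stats(nm_z$data, bg_cts)
  floor_nm <- nm_floor(bgst, thr_cfg, sd_ref = sd_ref)
  errors <- list()
  refined <- list()
  d2 <- dim(nm_z$data)[1:2]
  order_labels <- c("RN", "SN", "STN", "NM")
  items <- Filter(function(z) z$label %in% order_labels, zoomv)
  items <- items[order(match(vapply(items, `[[`, character(1), "label"),
                             order_labels))]
  masks <- list(RN = list(), SN = list())
  for (it in items) {
    key <- paste0(it$label, "/", it$hemisphere, "/", it$crop_slice)
    ct0 <- contour(it$crop_slice, it$vertices, label = it$label,
                   hemisphere = it$hemisphere)
    res <- tryCatch({
      if (it$label == "NM") {
        img <- nm_z$data[, , it$crop_slice]
        dpa_refine(img, ct0, dpa_cfg, intensity_floor = floor_nm,
                   structure_id = key)
      } else {
        img <- chi_z$data[, , it$crop_slice]
        qp <- qsm_prepare(img, ct0, thr_cfg)
        excl <- NULL
        if (it$label == "SN") {
          rm <- exclusion_mask(masks$RN, it$crop_slice, d2)
          excl <- rm
        } else if (it$label == "STN") {
          excl <- exclusion_mask(c(masks$RN, masks$SN), it$crop_slice, d2)
        }
        dpa_refine(qp$map, ct0, dpa_cfg,
                   intensity_floor = max(qp$threshold, 1e-6),
                   exclude_mask = excl, structure_id = key)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      next
    }
    if (it$label %in% c("RN", "SN"))
      masks[[it$label]] <- c(masks[[it$label]],
                             list(list(slice = it$crop_slice,
                                       mask = contour_to_mask(res, d2))))
    refined <- c(refined, list(
      contour(crop$crop_start + it$crop_slice - 1L,
              res$vertices / bundle$zoom,
              label = it$label, hemisphere = it$hemisphere)))
  }
  # carry mapped VTA and BG (not refined)
  for (z in zoomv) {
    if (!(z$label %in% c("VTA", "BG"))) next
    refined <- c(refined, list(
      contour(crop$crop_start + z$crop_slice - 1L, z$vertices / bundle$zoom,
              label = z$label, hemisphere = z$hemisphere)))
  }
  structure(list(structures = structure_set(refined), mapped = mapped,
                 background = bgst, errors = errors, crop = crop,
                 tf_global = tf_g, tf_local = tf_l),
            class = "segmentation_result")
}

exclusion_mask <- function(mask_list, slice, d2) {
  out <- NULL
  for (m in mask_list) {
    if (m$slice != slice) next
    out <- if (is.null(out)) m$mask else out | m$mask
  }
  out
}

#' Write / read a template bundle as a directory
#'
#' Volumes are stored as NIfTI, boundaries and background ROIs as JSON, and
#' scalar metadata as YAML.
#'
#' @param bundle a [template_bundle()].
#' @param dir target directory (created if missing).
#' @export
write_template_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$nm_zoom, file.path(dir, "nm.nii"))
  write_volume(bundle$qsm_zoom, file.path(dir, "qsm.nii"))
  write_volume(bundle$global_ref, file.path(dir, "global_ref.nii"))
  write_structures(bundle$boundaries, file.path(dir, "boundaries.json"))
  write_structures(bundle$bg_rois, file.path(dir, "bg.json"))
  yaml::write_yaml(list(windows = lapply(bundle$windows, as.integer),
                        ref_rn = bundle$ref_rn,
                        crop_start = bundle$crop_start, zoom = bundle$zoom,
                        n_subjects_averaged = bundle$n_subjects_averaged),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_template_bundle
#' @export
read_template_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  template_bundle(nm_zoom = read_volume(file.path(dir, "nm.nii")),
                  qsm_zoom = read_volume(file.path(dir, "qsm.nii")),
                  boundaries = read_structures(file.path(dir, "boundaries.json")),
                  bg_rois = read_structures(file.path(dir, "bg.json")),
                  windows = lapply(meta$windows, as.integer),
                  global_ref = read_volume(file.path(dir, "global_ref.nii")),
                  ref_rn = meta$ref_rn, crop_start = meta$crop_start,
                  zoom = meta$zoom,
                  n_subjects_averaged = meta$n_subjects_averaged)
}
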