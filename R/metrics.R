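#' DICE similarity coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)` between two binary masks on the same grid.
#'
#' @param a,b logical arrays of identical shape.
#' @return the coefficient in `[0, 1]`; two empty masks are an error.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    stop("dice: both masks are empty (undefined)", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

#' Volume ratio between an automatic and a manual segmentation
#'
#' Automatic volume divided by manual volume, both in mm^3 (voxel count
#' times voxel volume).
#'
#' @param auto_mask,manual_mask logical arrays on the same grid.
#' @param spacing voxel spacing in mm.
#' @return the ratio (dimensionless).
#' @export
volume_ratio <- function(auto_mask, manual_mask, spacing = c(1, 1, 1)) {
  vm <- sum(manual_mask) * prod(spacing)
  if (vm <= 0) stop("volume_ratio: manual volume is zero", call. = FALSE)
  sum(auto_mask) * prod(spacing) / vm
}

#' Total iron content of a structure
#'
#' Sums, over the slices the structure is drawn on, the product of the
#' slice volume and the mean susceptibility on that slice - algebraically
#' the voxel volume times the susceptibility sum over the mask.
#'
#' @param chi susceptibility [volume3d()] or array (ppb).
#' @param set a [structure_set()].
#' @param label structure to quantify; must be present.
#' @param hemisphere optional hemisphere filter.
#' @param spacing voxel spacing (taken from the volume if available).
#' @return total iron content in ppb mm^3.
#' @export
iron_content <- function(chi, set, label, hemisphere = NULL,
                         spacing = NULL) {
  a <- if (inherits(chi, "volume3d")) chi$data else chi
  if (is.null(spacing))
    spacing <- if (inherits(chi, "volume3d")) chi$spacing else c(1, 1, 1)
  sel <- ss_filter(set, label = label, hemisphere = hemisphere)
  if (!length(sel$contours))
    stop("iron_content: structure ", label, " not present", call. = FALSE)
  vox <- prod(spacing)
  tot <- 0
  for (ct in sel$contours) {
    m <- contour_to_mask(ct, dim(a)[1:2])
    tot <- tot + vox * sum(a[, , ct$slice][m])
  }
  tot
}

#' Total neuromelanin content of a structure
#'
#' Sums the product of per-slice NM volume and mean NM contrast (percent
#' over the background mean).
#'
#' @param nm NM magnitude [volume3d()] or array.
#' @param bg a [background_stats()].
#' @param set a [structure_set()] with NM contours.
#' @param label contour label to integrate (default `"NM"`).
#' @param hemisphere optional hemisphere filter.
#' @param spacing voxel spacing.
#' @return total NM content in percent mm^3.
#' @export
nm_content <- function(nm, bg, set, label = "NM", hemisphere = NULL,
                       spacing = NULL) {
  if (!inherits(bg, "background_stats"))
    stop("nm_content: background statistics required", call. = FALSE)
  a <- if (inherits(nm, "volume3d")) nm$data else nm
  if (is.null(spacing))
    spacing <- if (inherits(nm, "volume3d")) nm$spacing else c(1, 1, 1)
  sel <- ss_filter(set, label = label, hemisphere = hemisphere)
  vox <- prod(spacing)
  tot <- 0
  for (ct in sel$contours) {
    m <- contour_to_mask(ct, dim(a)[1:2])
    if (!any(m)) next
    contr <- mean(nm_contrast(a[, , ct$slice][m], bg))
    tot <- tot + vox * sum(m) * contr
  }
  tot
}

#' Derive the substantia nigra pars compacta
#'
#' The neuromelanin-bright territory comprises the SNpc plus the ventral
#' tegmental area, while the iron-rich SN comprises SNpc plus SNpr; their
#' overlap, after subtracting the VTA from the NM volume to fix the
#' anterior boundary, is taken as the SNpc:
#' `SNpc = (NM \ VTA) ∩ SN_iron`.
#'
#' @param nm_mask,sn_mask,vta_mask logical arrays on the same grid
#'   (`vta_mask` may be `NULL` for an empty VTA).
#' @return logical array, the SNpc mask.
#' @export
derive_snpc <- function(nm_mask, sn_mask, vta_mask = NULL) {
  stopifnot(all(dim(nm_mask) == dim(sn_mask)))
  if (is.null(vta_mask)) vta_mask <- array(FALSE, dim(nm_mask))
  nm_mask & !vta_mask & sn_mask
}

#' Per-structure evaluation of a segmentation against a reference
#'
#' Computes, per structure and hemisphere (plus their mean, since left and
#' right are conventionally averaged): volume, DICE against the reference,
#' volume ratio, mean susceptibility and iron content (QSM structures), or
#' mean contrast and NM content (NM structures).
#'
#' @param result [structure_set()] to evaluate (e.g. from
#'   [segment_subject()]).
#' @param reference [structure_set()] of reference (manual/truth) contours.
#' @param nm,chi subject volumes used for content measures (optional).
#' @param bg a [background_stats()] (needed for NM content).
#' @param dim volume dimensions (taken from `nm`/`chi` if given).
#' @return data.frame with one row per structure x hemisphere and a
#'   `"mean"` hemisphere row per structure.
#' @export
evaluate_structures <- function(result, reference, nm = NULL, chi = NULL,
                                bg = NULL, dim = NULL) {
  voln <- nm %||% chi
  if (is.null(dim)) dim <- base::dim(if (inherits(voln, "volume3d"))
    voln$data else voln)
  spacing <- if (inherits(voln, "volume3d")) voln$spacing else c(1, 1, 1)
  labs <- intersect(c("NM", "SN", "RN", "STN"), ss_labels(result))
  rows <- list()
  for (lab in labs) {
    per_h <- list()
    for (h in c("L", "R")) {
      ma <- structures_mask(result, dim, label = lab, hemisphere = h)
      mr <- structures_mask(reference, dim, label = lab, hemisphere = h)
      if (!any(ma) && !any(mr)) next
      dc <- dice(ma, mr)
      vr <- if (any(mr)) volume_ratio(ma, mr, spacing) else NA_real_
      vol <- sum(ma) * prod(spacing)
      mean_chi <- iron <- mean_ctr <- nmcont <- NA_real_
      if (lab %in% c("SN", "RN", "STN") && !is.null(chi)) {
        ca <- if (inherits(chi, "volume3d")) chi$data else chi
        if (any(ma)) mean_chi <- mean(ca[ma])
        iron <- if (any(ma)) iron_content(chi, result, lab, h) else 0
      }
      if (lab == "NM" && !is.null(nm) && !is.null(bg)) {
        na_ <- if (inherits(nm, "volume3d")) nm$data else nm
        if (any(ma)) mean_ctr <- mean(nm_contrast(na_[ma], bg))
        nmcont <- if (any(ma)) nm_content(nm, bg, result, lab, h) else 0
      }
      row <- data.frame(structure = lab, hemisphere = h, volume_mm3 = vol,
                        dice = dc, volume_ratio = vr, mean_chi_ppb = mean_chi,
                        iron_content = iron, mean_contrast_pct = mean_ctr,
                        nm_content = nmcont)
      per_h <- c(per_h, list(row))
    }
    if (length(per_h)) {
      all_h <- do.call(rbind, per_h)
      mrow <- all_h[1, ]
      mrow$hemisphere <- "mean"
      for (cn in setdiff(names(all_h), c("structure", "hemisphere")))
        mrow[[cn]] <- mean(all_h[[cn]], na.rm = TRUE)
      rows <- c(rows, list(all_h), list(mrow))
    }
  }
  do.call(rbind, rows)
}
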