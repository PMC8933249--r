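#' Closed per-slice boundary contour
#'
#' A closed subpixel polygon on one axial slice. Vertices live in continuous
#' in-plane voxel coordinates with pixel centers at integers (0-based), so the
#' pixel at array position `[i, j]` has its center at `(i - 1, j - 1)`. Slice
#' indices are ordinary 1-based R array indices. The polygon is always
#' treated as closed (last vertex connects back to the first).
#'
#' @param slice integer slice index (1-based).
#' @param vertices n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @param label structure label, one of `"NM"`, `"SN"`, `"RN"`, `"STN"`,
#'   `"VTA"`, `"BG"` (or any caller-defined label).
#' @param hemisphere `"L"` or `"R"` (optional).
#' @return An object of class `contour`.
#' @export
contour <- function(slice, vertices, label = NA_character_,
                    hemisphere = NA_character_) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3L)
    stop("contour: need at least 3 vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("contour: vertices must be finite", call. = FALSE)
  # drop duplicated closing vertex if present
  n <- nrow(vertices)
  if (all(abs(vertices[1, ] - vertices[n, ]) < 1e-12) && n > 3L)
    vertices <- vertices[-n, , drop = FALSE]
  structure(list(slice = as.integer(slice), vertices = vertices,
                 label = label, hemisphere = hemisphere),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %s/%s slice %d, %d vertices, area %.1f px\n",
              x$label, x$hemisphere, x$slice, nrow(x$vertices),
              polygon_area(x$vertices)))
  invisible(x)
}

#' Shoelace area of a closed polygon
#'
#' @param vertices n x 2 matrix (closed implicitly).
#' @return absolute enclosed area in squared pixel units.
#' @export
polygon_area <- function(vertices) {
  v <- matrix(as.numeric(vertices), ncol = 2)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_perimeter <- function(vertices) {
  v <- matrix(as.numeric(vertices), ncol = 2)
  v2 <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((v2 - v)^2)))
}

# signed area > 0 means counter-clockwise in the (x, y) frame
polygon_signed_area <- function(vertices) {
  v <- matrix(as.numeric(vertices), ncol = 2)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Set of labelled contours grouped by structure and hemisphere
#'
#' @param contours list of [contour()] objects.
#' @return An object of class `structure_set` (a list of contours).
#' @export
structure_set <- function(contours = list()) {
  if (inherits(contours, "contour")) contours <- list(contours)
  stopifnot(all(vapply(contours, inherits, logical(1), "contour")))
  structure(list(contours = contours), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  if (!length(x$contours)) { cat("<structure_set> empty\n"); return(invisible(x)) }
  lab <- vapply(x$contours, function(ct) paste0(ct$label, "/", ct$hemisphere),
                character(1))
  tab <- table(lab)
  cat("<structure_set>", length(x$contours), "contours:",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.structure_set <- function(x) length(x$contours)

#' Filter a structure set by label, hemisphere and/or slice
#'
#' @param set a [structure_set()].
#' @param label,hemisphere,slice optional filters; `NULL` keeps everything.
#' @return a [structure_set()] with the matching contours.
#' @export
ss_filter <- function(set, label = NULL, hemisphere = NULL, slice = NULL) {
  keep <- vapply(set$contours, function(ct) {
    (is.null(label) || ct$label %in% label) &&
      (is.null(hemisphere) || ct$hemisphere %in% hemisphere) &&
      (is.null(slice) || ct$slice %in% slice)
  }, logical(1))
  structure_set(set$contours[keep])
}

#' @rdname ss_filter
#' @export
ss_slices <- function(set) sort(unique(vapply(set$contours, `[[`, integer(1),
                                              "slice")))

ss_labels <- function(set) unique(vapply(set$contours, `[[`, character(1),
                                         "label"))

ss_bind <- function(...) {
  sets <- list(...)
  structure_set(unlist(lapply(sets, function(s) {
    if (inherits(s, "structure_set")) s$contours
    else if (inherits(s, "contour")) list(s)
    else s
  }), recursive = FALSE))
}

#' Validate the structural invariants of a structure set
#'
#' Checks that per structure/hemisphere the slice indices are unique and
#' increasing, that every contour has at least 3 finite vertices, and that
#' background (BG) contours never overlap NM contours on the same slice.
#'
#' @param set a [structure_set()].
#' @param grid_dim optional in-plane grid dimension for the overlap check.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_structures <- function(set, grid_dim = NULL) {
  key <- vapply(set$contours, function(ct) paste0(ct$label, "/", ct$hemisphere),
                character(1))
  for (k in unique(key)) {
    sl <- vapply(set$contours[key == k], `[[`, integer(1), "slice")
    if (anyDuplicated(sl))
      stop("validate_structures: duplicated slice for ", k, call. = FALSE)
  }
  if (!is.null(grid_dim)) {
    bg <- ss_filter(set, label = "BG")
    nm <- ss_filter(set, label = "NM")
    for (ct in bg$contours) {
      for (cn in nm$contours[vapply(nm$contours, function(z) z$slice == ct$slice,
                                    logical(1))]) {
        m1 <- contour_to_mask(ct, grid_dim)
        m2 <- contour_to_mask(cn, grid_dim)
        if (any(m1 & m2))
          stop("validate_structures: BG contour overlaps NM on slice ",
               ct$slice, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Rasterize a contour to a binary in-plane mask
#'
#' Pixels whose centers fall inside the polygon (or within a hair of its
#' boundary) are set. The inverse, [mask_to_contour()], traces subpixel
#' iso-contours of the mask at level 0.5; the round trip preserves the area
#' of convex regions to within 2%.
#'
#' @param ct a [contour()] or an n x 2 vertex matrix.
#' @param grid_dim length-2 integer (nx, ny) of the target grid.
#' @return logical nx x ny matrix.
#' @export
contour_to_mask <- function(ct, grid_dim) {
  v <- if (inherits(ct, "contour")) ct$vertices else matrix(ct, ncol = 2)
  if (nrow(v) < 3L) stop("contour_to_mask: degenerate polygon", call. = FALSE)
  if (cpp_poly_self_intersects(v))
    stop("contour_to_mask: self-intersecting polygon", call. = FALSE)
  nx <- as.integer(grid_dim[1]); ny <- as.integer(grid_dim[2])
  if (any(v[, 1] < -0.5 - 1e-9) || any(v[, 1] > nx - 0.5 + 1e-9) ||
      any(v[, 2] < -0.5 - 1e-9) || any(v[, 2] > ny - 0.5 + 1e-9))
    stop("contour_to_mask: contour extends outside the grid", call. = FALSE)
  cpp_poly_mask(v, nx, ny, 1e-7)
}

#' @param mask logical/numeric 2D matrix.
#' @param slice slice index recorded on the returned contours.
#' @param label,hemisphere labels recorded on the returned contours.
#' @rdname contour_to_mask
#' @export
mask_to_contour <- function(mask, slice = 1L, label = NA_character_,
                            hemisphere = NA_character_) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  # pad so border-touching blobs still close
  mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)) - 2,
                                y = seq_len(ncol(mp)) - 2,
                                z = mp, levels = 0.5)
  out <- lapply(cl, function(g) {
    v <- cbind(g$x, g$y)
    if (nrow(v) < 3L) return(NULL)
    contour(slice, v, label = label, hemisphere = hemisphere)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Rasterize selected structures to a 3D binary mask
#'
#' @param set a [structure_set()].
#' @param dim length-3 volume dimensions.
#' @param label,hemisphere optional filters (see [ss_filter()]).
#' @return logical array of `dim`.
#' @export
structures_mask <- function(set, dim, label = NULL, hemisphere = NULL) {
  sel <- ss_filter(set, label = label, hemisphere = hemisphere)
  out <- array(FALSE, dim)
  for (ct in sel$contours) {
    if (ct$slice < 1L || ct$slice > dim[3]) next
    out[, , ct$slice] <- out[, , ct$slice] | contour_to_mask(ct, dim[1:2])
  }
  out
}

#' Rasterize a structure set to an integer label mask volume
#'
#' Later labels overwrite earlier ones where contours overlap. The legend
#' maps label names to integer codes.
#'
#' @param set a [structure_set()].
#' @param dim length-3 volume dimensions.
#' @param legend named integer vector label -> code; defaults to the order of
#'   appearance.
#' @return list with `volume` (a [volume3d()] of integer codes) and `legend`.
#' @export
rasterize_structures <- function(set, dim, legend = NULL) {
  labs <- ss_labels(set)
  if (is.null(legend)) legend <- stats::setNames(seq_along(labs), labs)
  a <- array(0L, dim)
  for (ct in set$contours) {
    if (!(ct$label %in% names(legend)) || ct$slice < 1L || ct$slice > dim[3]) next
    m <- contour_to_mask(ct, dim[1:2])
    sl <- a[, , ct$slice]
    sl[m] <- legend[[ct$label]]
    a[, , ct$slice] <- sl
  }
  list(volume = volume3d(a), legend = legend)
}

#' Serialize / read a structure set as JSON
#'
#' One record per contour: `{label, hemisphere, slice, vertices: [[x, y], ...]}`.
#'
#' @param set a [structure_set()].
#' @param path output (input) JSON path.
#' @export
write_structures <- function(set, path) {
  recs <- lapply(set$contours, function(ct) {
    list(label = ct$label, hemisphere = ct$hemisphere, slice = ct$slice,
         vertices = unname(apply(ct$vertices, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structures
#' @export
read_structures <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure_set(lapply(recs, function(r) {
    v <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
    contour(r$slice, v, label = r$label %||% NA_character_,
            hemisphere = r$hemisphere %||% NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign hemispheres by the mid-sagittal plane
#'
#' Structures whose centroid lies at x below the volume's in-plane midline
#' are labelled `"L"`, the rest `"R"`.
#'
#' @param set a [structure_set()].
#' @param nx in-plane x dimension of the volume the contours live on.
#' @return the structure set with hemisphere fields filled in.
#' @export
assign_hemispheres <- function(set, nx) {
  mid <- (nx - 1) / 2
  structure_set(lapply(set$contours, function(ct) {
    ct$hemisphere <- if (mean(ct$vertices[, 1]) < mid) "L" else "R"
    ct
  }))
}

# uniform arc-length resampling of a closed polygon to n vertices
resample_closed <- function(vertices, n) {
  v <- matrix(as.numeric(vertices), ncol = 2)
  v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(matrix(rep(v[1, ], n), ncol = 2, byrow = TRUE))
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(at, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(v)] <- nrow(v) - 1
  f <- (at - cum[idx]) / pmax(seg[idx], 1e-12)
  v[idx, , drop = FALSE] * (1 - f) + v[idx + 1, , drop = FALSE] * f
}

# circular moving-average smoothing of a closed polygon
smooth_closed <- function(vertices, k = 5L) {
  v <- matrix(as.numeric(vertices), ncol = 2)
  n <- nrow(v)
  if (n <= k) return(v)
  h <- (k - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i - 1 + o) %% n) + 1)
  cbind(rowMeans(matrix(v[idx, 1], n)), rowMeans(matrix(v[idx, 2], n)))
}
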