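#' Configuration for the dynamic-programming boundary refinement
#'
#' The refinement locks an initial closed boundary onto image edges by
#' solving, per iteration, a cyclic shortest-path problem over candidate
#' positions sampled along profiles normal to the structure. The cost
#' balances the (outward directional) signal gradient against the local
#' radius of curvature of the candidate polyline.
#'
#' @param alpha curvature weight; larger values smooth the boundary more
#'   (default 0.10).
#' @param search_radius_px maximum excursion of a vertex along its profile
#'   per iteration, in pixels (default 6, intended for x4-zoomed images).
#' @param n_profiles number of boundary sample points; `NULL` (default)
#'   means `max(64, round(perimeter))`, i.e. roughly one profile per pixel
#'   of arc length.
#' @param n_iterations number of refine iterations (default 5).
#' @param background_offset constant added to supra-threshold signal before
#'   gradient computation, sharpening the step against zeroed background and
#'   keeping the search radius small and safe (default 1000).
#' @param adaptive_otsu if `TRUE`, re-estimate the intensity floor each
#'   iteration by Otsu analysis of the pixels inside the current boundary's
#'   bounding box.
#' @return A list of class `dpa_config`.
#' @export
dpa_config <- function(alpha = 0.10, search_radius_px = 6L, n_profiles = NULL,
                       n_iterations = 5L, background_offset = 1000,
                       adaptive_otsu = FALSE) {
  stopifnot(alpha >= 0, search_radius_px >= 1,
            is.null(n_profiles) || n_profiles >= 16,
            n_iterations >= 0)
  structure(list(alpha = alpha, search_radius_px = as.integer(search_radius_px),
                 n_profiles = n_profiles, n_iterations = as.integer(n_iterations),
                 background_offset = background_offset,
                 adaptive_otsu = isTRUE(adaptive_otsu)),
            class = "dpa_config")
}

#' Hand-built profile graph
#'
#' Assembles a profile graph directly from cost arrays, mainly for testing
#' the solver against exhaustive enumeration. `node[i, k]` is the cost of
#' candidate `k` on profile `i`; `edge[i, a, b]` the cost of the transition
#' from candidate `a` on profile `i` to candidate `b` on profile `i + 1`
#' (profile `n` wraps to 1).
#'
#' @param node n x K node-cost matrix.
#' @param edge n x K x K edge-cost array, or `NULL` for zero edge costs.
#' @param triple optional n x K x K x K second-order cost array:
#'   `triple[i, a, b, c]` is added at vertex `i` when profiles
#'   `i - 1, i, i + 1` take candidates `a, b, c`.
#' @param offsets numeric candidate offsets (used for tie-breaking; defaults
#'   to centered integer offsets).
#' @param positions optional list with `x`, `y` n x K candidate coordinate
#'   matrices, so that [dpa_solve()] can return a contour.
#' @return An object of class `profile_graph`.
#' @export
profile_graph <- function(node, edge = NULL, triple = NULL, offsets = NULL,
                          positions = NULL) {
  node <- as.matrix(node)
  n <- nrow(node); K <- ncol(node)
  if (is.null(edge)) edge <- array(0, c(n, K, K))
  stopifnot(all(dim(edge) == c(n, K, K)))
  if (!is.null(triple)) stopifnot(all(dim(triple) == c(n, K, K, K)))
  if (is.null(offsets)) offsets <- seq_len(K) - (K + 1) / 2
  structure(list(node = node, edge = edge, triple = triple,
                 offsets = as.numeric(offsets), positions = positions),
            class = "profile_graph")
}

#' Build the profile graph for boundary refinement
#'
#' Samples `n_profiles` outward profiles normal to (a smoothed version of)
#' the initial boundary, each with `2 * search_radius + 1` candidate
#' positions at 1 px steps. Node cost is the negated per-profile-normalized
#' magnitude of the outward directional gradient (central differences of
#' bilinear samples); the transition cost between adjacent profiles is
#' `|delta offset| / search_radius` plus `alpha` times the discrete
#' curvature (inverse circumradius) of each candidate vertex triple.
#' Candidates falling outside the image get infinite cost.
#'
#' @param image 2D numeric matrix.
#' @param init_contour a [contour()] or n x 2 vertex matrix (closed).
#' @param config a [dpa_config()].
#' @param base_points,directions optional n x 2 matrices overriding the
#'   profile anchors and (unit) profile directions, e.g. to anchor profiles
#'   on the thinned centerline of an elongated structure.
#' @return A `profile_graph` carrying candidate positions.
#' @export
build_profile_graph <- function(image, init_contour, config = dpa_config(),
                                base_points = NULL, directions = NULL) {
  v <- if (inherits(init_contour, "contour")) init_contour$vertices
       else matrix(init_contour, ncol = 2)
  r <- config$search_radius_px
  nx <- nrow(image); ny <- ncol(image)
  if (is.null(base_points)) {
    np <- config$n_profiles %||% max(64L, as.integer(round(polygon_perimeter(v))))
    vs <- smooth_closed(v, 5L)
    base <- resample_closed(vs, np)
  } else {
    base <- matrix(base_points, ncol = 2)
    np <- nrow(base)
  }
  if (any(base[, 1] < 0) || any(base[, 1] > nx - 1) ||
      any(base[, 2] < 0) || any(base[, 2] > ny - 1))
    stop("build_profile_graph: contour touches the image border", call. = FALSE)
  if (is.null(directions)) {
    # outward normals of the (CCW-oriented) resampled boundary
    if (polygon_signed_area(base) < 0) base <- base[rev(seq_len(np)), ]
    nxt <- rbind(base[-1, , drop = FALSE], base[1, , drop = FALSE])
    prv <- rbind(base[np, , drop = FALSE], base[-np, , drop = FALSE])
    tang <- nxt - prv
    len <- pmax(sqrt(rowSums(tang^2)), 1e-12)
    dirs <- cbind(tang[, 2] / len, -tang[, 1] / len)
  } else {
    dirs <- matrix(directions, ncol = 2)
    len <- pmax(sqrt(rowSums(dirs^2)), 1e-12)
    dirs <- dirs / len
  }
  offsets <- seq.int(-r, r)
  K <- length(offsets)
  # sample at half-integer offsets so the gradient aperture is one pixel:
  # g(o) = v(o + 1/2) - v(o - 1/2) peaks exactly at an ideal step edge
  off_ext <- seq(-r - 0.5, r + 0.5, by = 1)
  ex <- outer(base[, 1], rep(1, K + 1)) + outer(dirs[, 1], off_ext)
  ey <- outer(base[, 2], rep(1, K + 1)) + outer(dirs[, 2], off_ext)
  vals <- matrix(cpp_interp2(image, as.numeric(ex), as.numeric(ey)), np, K + 1)
  g <- vals[, 2:(K + 1), drop = FALSE] - vals[, 1:K, drop = FALSE]
  gm <- abs(g)
  eps_g <- 1e-9 * max(1, max(abs(vals)))
  gmax0 <- apply(gm, 1, max)
  gmax0[gmax0 < eps_g] <- 0
  node <- -gm / pmax(gmax0, 1e-12)
  node[gmax0 == 0, ] <- 0
  # profiles with no usable gradient (flat, e.g. spanning zeroed background
  # beyond a concave edge) drift gently inward, toward the centerline, so
  # the boundary can creep across featureless gaps over the iterations;
  # a globally constant image keeps all node costs equal
  gref <- max(gmax0)
  if (gref > 0) {
    flat <- gmax0 == 0
    if (any(flat))
      node[flat, ] <- matrix(0.2 * (offsets + r) / (2 * r),
                             sum(flat), K, byrow = TRUE)
  }
  cx <- outer(base[, 1], rep(1, K)) + outer(dirs[, 1], offsets)
  cy <- outer(base[, 2], rep(1, K)) + outer(dirs[, 2], offsets)
  outside <- cx < 0 | cx > nx - 1 | cy < 0 | cy > ny - 1
  node[outside] <- Inf
  # first-order smoothness between adjacent profiles
  dd <- abs(outer(offsets, offsets, "-")) / r
  edge <- array(rep(dd, each = np), c(np, K, K))
  triple <- NULL
  if (config$alpha > 0) {
    triple <- array(0, c(np, K, K, K))
    expand_ab <- function(m) array(m, c(K, K, K))               # (a, b) -> (a, b, c)
    expand_ac <- function(m) aperm(array(m, c(K, K, K)), c(1, 3, 2)) # (a, c)
    expand_bc <- function(m) aperm(array(m, c(K, K, K)), c(3, 1, 2)) # (b, c)
    for (i in seq_len(np)) {
      ip <- if (i == 1L) np else i - 1L
      io <- if (i == np) 1L else i + 1L
      Ax <- cx[ip, ]; Ay <- cy[ip, ]
      Bx <- cx[i, ];  By <- cy[i, ]
      Cx <- cx[io, ]; Cy <- cy[io, ]
      ABx <- outer(Ax, Bx, function(a, b) b - a); ABy <- outer(Ay, By, function(a, b) b - a)
      ACx <- outer(Ax, Cx, function(a, b) b - a); ACy <- outer(Ay, Cy, function(a, b) b - a)
      BCx <- outer(Bx, Cx, function(a, b) b - a); BCy <- outer(By, Cy, function(a, b) b - a)
      cross <- expand_ab(ABx) * expand_ac(ACy) - expand_ab(ABy) * expand_ac(ACx)
      d12 <- expand_ab(sqrt(ABx^2 + ABy^2))
      d23 <- expand_bc(sqrt(BCx^2 + BCy^2))
      d31 <- expand_ac(sqrt(ACx^2 + ACy^2))
      # dimensionless curvature: reference radius (5 px) over the local
      # circumradius of the candidate triple
      kappa <- 5 * 2 * abs(cross) / pmax(d12 * d23 * d31, 1e-9)
      triple[i, , , ] <- config$alpha * kappa
    }
  }
  structure(list(node = node, edge = edge, triple = triple,
                 offsets = offsets, positions = list(x = cx, y = cy),
                 base = base, dirs = dirs, gradmag = gm, config = config),
            class = "profile_graph")
}

#' Solve the cyclic shortest-path problem over a profile graph
#'
#' Finds the minimum-cost closed path visiting one candidate per profile.
#' For first-order (pairwise) graphs the solution is globally optimal: the
#' forward dynamic program is repeated for every possible start offset and
#' the overall minimum kept. With second-order (curvature) costs the DP runs
#' over candidate-pair states; one of the two wrap-around curvature terms is
#' omitted, which keeps the solver exact for pairwise graphs and
#' near-optimal otherwise. Deterministic: ties are broken toward the
#' smaller absolute offset, then the smaller candidate index.
#'
#' @param graph a `profile_graph` from [build_profile_graph()] or
#'   [profile_graph()].
#' @return list with `path` (chosen candidate index per profile), `offsets`
#'   (the corresponding offsets), `cost`, and - when the graph carries
#'   candidate positions - `vertices` (n x 2 refined contour).
#' @export
dpa_solve <- function(graph) {
  stopifnot(inherits(graph, "profile_graph"))
  node <- graph$node
  n <- nrow(node); K <- ncol(node)
  bad <- apply(node, 1, function(r) all(!is.finite(r)))
  if (any(bad))
    stop("dpa_solve: profile ", which(bad)[1], " has no feasible candidate",
         call. = FALSE)
  ord <- order(abs(graph$offsets), seq_len(K)) - 1L
  if (is.null(graph$triple)) {
    sol <- cpp_dp_cyclic_first(node, as.numeric(graph$edge), as.integer(ord))
  } else {
    sol <- cpp_dp_cyclic_second(node, as.numeric(graph$edge),
                                as.numeric(aperm(graph$triple, c(2, 1, 3, 4))),
                                as.integer(ord))
  }
  if (!isTRUE(sol$feasible))
    stop("dpa_solve: no feasible closed path", call. = FALSE)
  path <- as.integer(sol$path)
  out <- list(path = path, offsets = graph$offsets[path], cost = sol$cost)
  if (!is.null(graph$positions)) {
    idx <- cbind(seq_len(n), path)
    out$vertices_raw <- cbind(graph$positions$x[idx], graph$positions$y[idx])
    off <- graph$offsets[path]
    if (!is.null(graph$gradmag)) {
      # parabolic subpixel refinement of the gradient peak along each profile
      K <- length(graph$offsets)
      delta <- numeric(n)
      for (i in seq_len(n)) {
        o <- path[i]
        if (o > 1L && o < K) {
          m1 <- graph$gradmag[i, o - 1L]; m0 <- graph$gradmag[i, o]
          p1 <- graph$gradmag[i, o + 1L]
          den <- m1 - 2 * m0 + p1
          if (is.finite(den) && den < -1e-12)
            delta[i] <- max(-0.5, min(0.5, (m1 - p1) / (2 * den)))
        }
      }
      off <- off + delta
    }
    out$vertices <- graph$base + graph$dirs * off
    out$offsets <- off
  }
  out
}

#' Iterative dynamic-programming boundary refinement
#'
#' Runs `n_iterations` of: (a) zero all pixels below the intensity floor and
#' offset the surviving signal by `background_offset`; (b) rasterize the
#' current boundary and thin the enclosed supra-floor region to its
#' centerline; (c) re-anchor the profiles on the current boundary with
#' directions radiating outward from the nearest centerline pixel; (d) solve
#' the cyclic shortest-path problem. No vertex moves more than
#' `search_radius_px` per iteration, bounding the total excursion from the
#' initial boundary.
#'
#' @param image 2D numeric matrix.
#' @param init_contour a [contour()] or n x 2 vertex matrix.
#' @param config a [dpa_config()].
#' @param intensity_floor pixels strictly below this are zeroed before the
#'   gradient computation. `NULL`: no flooring unless
#'   `config$adaptive_otsu` is set, in which case the floor is re-estimated
#'   each iteration by Otsu analysis inside the current region.
#' @param exclude_mask optional logical matrix; `TRUE` pixels are zeroed
#'   (e.g. the red nucleus interior when refining the substantia nigra, to
#'   prevent leakage across abutting structures).
#' @param structure_id label used in error messages.
#' @return A [contour()] (same slice/label as the input if it was a
#'   contour), with attribute `area_trace`: the enclosed pixel count after
#'   each iteration.
#' @export
dpa_refine <- function(image, init_contour, config = dpa_config(),
                       intensity_floor = NULL, exclude_mask = NULL,
                       structure_id = "structure") {
  is_ct <- inherits(init_contour, "contour")
  v <- if (is_ct) init_contour$vertices else matrix(init_contour, ncol = 2)
  grid <- dim(image)
  areas <- numeric(0)
  v_raw <- v
  for (it in seq_len(max(config$n_iterations, 1L))) {
    floor_i <- intensity_floor
    if (config$adaptive_otsu) {
      inb <- bbox_mask(v, grid, margin = config$search_radius_px)
      px <- image[inb]
      floor_i <- if (length(unique(px)) > 1) otsu_threshold(px) else NULL
    }
    work <- image
    if (!is.null(exclude_mask)) work[exclude_mask] <- 0
    if (!is.null(floor_i)) {
      keep <- work >= floor_i
      work <- (work + config$background_offset) * keep
    }
    cmask <- cpp_poly_mask(v, grid[1], grid[2], 1e-7)
    inside <- cmask & work > 0
    if (sum(inside) < 5)
      stop(sprintf("dpa_refine: %s collapsed (area %d px after thresholding)",
                   structure_id, sum(inside)), call. = FALSE)
    # thin only the populated bounding box (thinning cost scales with area)
    w <- which(inside, arr.ind = TRUE)
    i0 <- max(1L, min(w[, 1]) - 1L); i1 <- min(grid[1], max(w[, 1]) + 1L)
    j0 <- max(1L, min(w[, 2]) - 1L); j1 <- min(grid[2], max(w[, 2]) + 1L)
    cl <- thin_mask(inside[i0:i1, j0:j1, drop = FALSE])
    cp <- centerline_points(cl)
    cp[, 1] <- cp[, 1] + (i0 - 1L)
    cp[, 2] <- cp[, 2] + (j0 - 1L)
    if (it == 1L) {
      # uniform profiles along the (smoothed) initial boundary; later
      # iterations keep profile identities so a converged boundary is a
      # fixed point of the update
      np <- config$n_profiles %||%
        max(64L, as.integer(round(polygon_perimeter(v))))
      v <- resample_closed(smooth_closed(v, 5L), np)
    }
    np <- nrow(v)
    base <- v
    # profile directions: outward normals of the (smoothed) current
    # boundary, with the outward sign re-anchored on the centerline - the
    # nearest centerline pixel must lie on the inward side
    vs <- smooth_closed(base, 5L)
    nxt <- rbind(vs[-1, , drop = FALSE], vs[1, , drop = FALSE])
    prv <- rbind(vs[np, , drop = FALSE], vs[-np, , drop = FALSE])
    tang <- nxt - prv
    tl <- pmax(sqrt(rowSums(tang^2)), 1e-12)
    orient <- if (polygon_signed_area(vs) >= 0) 1 else -1
    dirs <- orient * cbind(tang[, 2] / tl, -tang[, 1] / tl)
    for (i in seq_len(np)) {
      j <- which.min((cp[, 1] - base[i, 1])^2 + (cp[, 2] - base[i, 2])^2)
      inward <- cp[j, ] - base[i, ]
      if (sum(inward^2) > 1e-8 && sum(dirs[i, ] * inward) > 0)
        dirs[i, ] <- -dirs[i, ]
    }
    graph <- build_profile_graph(work, v, config, base_points = base,
                                 directions = dirs)
    sol <- dpa_solve(graph)
    v <- sol$vertices
    v_raw <- sol$vertices_raw
    if (cpp_poly_self_intersects(v)) v <- repair_polygon(v, grid)
    areas <- c(areas, sum(cpp_poly_mask(v, grid[1], grid[2], 1e-7)))
    if (config$n_iterations == 0L) break
  }
  out <- if (is_ct) contour(init_contour$slice, v, label = init_contour$label,
                            hemisphere = init_contour$hemisphere)
         else contour(1L, v)
  attr(out, "area_trace") <- areas
  attr(out, "vertices_raw") <- v_raw
  out
}

# replace a (slightly) self-intersecting polygon by the traced outline of
# its even-odd rasterization, keeping the largest component
repair_polygon <- function(v, grid) {
  m <- cpp_poly_mask(v, grid[1], grid[2], 1e-7)
  if (!any(m)) return(v)
  lab <- EBImage::bwlabel(m)
  m <- lab == which.max(tabulate(lab[lab > 0]))
  cts <- mask_to_contour(m)
  if (!length(cts)) return(v)
  areas <- vapply(cts, function(ct) polygon_area(ct$vertices), numeric(1))
  cts[[which.max(areas)]]$vertices
}

bbox_mask <- function(vertices, grid, margin = 0) {
  i0 <- max(1, floor(min(vertices[, 1]) + 1 - margin))
  i1 <- min(grid[1], ceiling(max(vertices[, 1]) + 1 + margin))
  j0 <- max(1, floor(min(vertices[, 2]) + 1 - margin))
  j1 <- min(grid[2], ceiling(max(vertices[, 2]) + 1 + margin))
  m <- matrix(FALSE, grid[1], grid[2])
  m[i0:i1, j0:j1] <- TRUE
  m
}
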