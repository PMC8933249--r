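test_that("Zhang-Suen thinning produces 1-px idempotent centerlines", {
  bar <- matrix(FALSE, 30, 10); bar[6:25, 4:6] <- TRUE
  cl <- thin_mask(bar)
  expect_true(sum(cl) >= 15 && sum(cl) <= 22)   # ~1 px chain of length ~20
  expect_identical(unclass(thin_mask(cl)), unclass(cl))  # idempotent

  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_equal(sum(thin_mask(px)), 1)

  rr <- outer(1:60, 1:60, function(i, j) sqrt((i - 30)^2 + (j - 30)^2))
  ann <- rr > 10 & rr < 18
  cl2 <- thin_mask(ann)
  # topology preserved: one 8-connected loop enclosing one hole
  expect_equal(count_components8(unclass(cl2)), 1)
  expect_equal(count_components8(!cl2, conn = 4L), 2)  # inside + outside

  expect_error(thin_mask(matrix(FALSE, 4, 4)), "empty")
})

test_that("thinning idempotence holds on random blobs", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(FALSE, 40, 40)
    for (b in 1:3) {
      c0 <- sample(8:32, 2)
      r0 <- sample(3:8, 1)
      m <- m | outer(1:40, 1:40, function(x, y)
        (x - c0[1])^2 + (y - c0[2])^2 <= r0^2)
    }
    t1 <- thin_mask(m)
    expect_identical(unclass(thin_mask(t1)), unclass(t1))
  }
})

test_that("profile graph costs behave on flat, step and circular images", {
  cfgn <- dpa_config(alpha = 0)
  # constant image: all node costs equal
  const <- matrix(5, 80, 80)
  init <- circle_contour(40, 40, 15)$vertices
  g <- build_profile_graph(const, init, cfgn)
  expect_lt(diff(range(g$node)), 1e-12)

  # ideal step edge: minimum node cost exactly at the edge offset
  step <- matrix(100, 80, 80); step[, 1:40] <- 200
  init2 <- rbind(c(20, 39.5 - 5), c(60, 39.5 - 5), c(60, 39.5 + 5),
                 c(20, 39.5 + 5))
  # horizontal profiles crossing y = 39.5: use explicit bases on the edge
  base <- cbind(seq(25, 55, length.out = 20), 39.5)
  dirs <- cbind(rep(0, 20), rep(1, 20))
  g2 <- build_profile_graph(step, init2, cfgn, base_points = base,
                            directions = dirs)
  expect_true(all(apply(g2$node, 1, which.min) == which(g2$offsets == 0)))

  # circle edge radius 30 from init radius 27: min cost at +3 on all profiles
  disk <- outer(0:99, 0:99, function(i, j)
    ifelse((i - 50)^2 + (j - 50)^2 <= 30^2, 200, 100)) * 1.0
  g3 <- build_profile_graph(disk, circle_contour(50, 50, 27)$vertices, cfgn)
  off_min <- g3$offsets[apply(g3$node, 1, which.min)]
  expect_true(all(off_min %in% c(3, 4)))

  # contour touching the border is a geometry error
  expect_error(build_profile_graph(disk, circle_contour(50, 50, 49.8)$vertices,
                                   cfgn), "border")
})

test_that("dpa_solve is exact against brute force and handles contracts", {
  # forced single zero-cost candidate per profile
  node <- matrix(10, 5, 3)
  pick <- c(1, 3, 2, 2, 1)
  node[cbind(1:5, pick)] <- 0
  g <- profile_graph(node)
  expect_equal(dpa_solve(g)$path, pick)

  set.seed(11)
  for (t in 1:30) {
    n <- sample(3:6, 1); K <- sample(2:4, 1)
    node <- matrix(runif(n * K), n, K)
    edge <- array(runif(n * K * K), c(n, K, K))
    s <- dpa_solve(profile_graph(node, edge))
    b <- brute_force_cycle(node, edge)
    expect_equal(s$cost, b$cost, tolerance = 1e-10)
  }

  # infeasible column
  node2 <- matrix(1, 4, 3); node2[2, ] <- Inf
  expect_error(dpa_solve(profile_graph(node2)), "feasible")
})

test_that("refinement recovers a noisy circle radius within 1 px", {
  set.seed(5)
  disk <- outer(0:99, 0:99, function(i, j)
    ifelse((i - 50)^2 + (j - 50)^2 <= 30^2, 200, 100)) +
    matrix(rnorm(10000, 0, 100 / 7), 100, 100)
  ct <- dpa_refine(disk, circle_contour(50, 50, 33)$vertices, dpa_config(),
                   intensity_floor = otsu_threshold(disk))
  r <- sqrt(rowSums(sweep(ct$vertices, 2, c(50, 50))^2))
  expect_lt(abs(mean(r) - 30), 1)
})

test_that("an initial contour already on a noise-free edge stays put", {
  disk <- outer(0:99, 0:99, function(i, j)
    ifelse((i - 50)^2 + (j - 50)^2 <= 30^2, 200, 100)) * 1.0
  init <- circle_contour(50, 50, 29.93)$vertices
  ct <- dpa_refine(disk, init, dpa_config(n_iterations = 1),
                   intensity_floor = 150)
  moved <- sqrt(rowSums((resample_closed(init, nrow(ct$vertices)) -
                           ct$vertices)^2))
  expect_lt(max(moved), 0.75)   # at most sub-pixel adjustment
})

test_that("refined boundary stays within the leakage bound", {
  set.seed(9)
  cfg <- dpa_config()
  p <- make_shape_phantom("rectangle", cnr = 7, seed = 9)
  ct <- dpa_refine(p$image, p$init_contour, cfg,
                   intensity_floor = otsu_threshold(p$image))
  init_rs <- resample_closed(p$init_contour$vertices, nrow(ct$vertices))
  d2 <- vapply(seq_len(nrow(ct$vertices)), function(i)
    min(sqrt(rowSums(sweep(init_rs, 2, ct$vertices[i, ])^2))), numeric(1))
  expect_lt(max(d2), cfg$search_radius_px * cfg$n_iterations + 1e-6)
})

test_that("refinement reports a collapse for degenerate thresholds", {
  img <- matrix(0, 60, 60)   # nothing survives any positive floor
  expect_error(
    dpa_refine(img, circle_contour(30, 30, 12)$vertices, dpa_config(),
               intensity_floor = 1, structure_id = "SN/L"),
    "SN/L")
})
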