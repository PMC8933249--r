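test_that("NIfTI round trip preserves data, spacing and errors on non-3D", {
  v <- volume3d(array(seq_len(8 * 8 * 4) * 1.0, c(8, 8, 4)),
                spacing = c(0.67, 1.34, 2))
  f <- tempfile(fileext = ".nii")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$data, v$data)
  expect_lt(max(abs(r$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(r$affine - v$affine)), 1e-6)

  f4 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), "3D")
})

test_that("contour/mask conversion matches analytic areas", {
  sq <- contour(1, rbind(c(-0.5, -0.5), c(9.5, -0.5), c(9.5, 9.5), c(-0.5, 9.5)))
  expect_equal(sum(contour_to_mask(sq, c(12, 12))), 100)

  circ <- circle_contour(30, 30, 20, n = 200)
  m <- contour_to_mask(circ, c(61, 61))
  expect_lt(abs(sum(m) - pi * 400) / (pi * 400), 0.02)

  two <- matrix(FALSE, 40, 40)
  two[5:10, 5:10] <- TRUE; two[25:32, 25:30] <- TRUE
  expect_length(mask_to_contour(two), 2)

  bow <- rbind(c(0, 0), c(5, 5), c(5, 0), c(0, 5))
  expect_error(contour_to_mask(bow, c(10, 10)), "self-intersecting")
})

test_that("mask -> contour -> mask round trip keeps convex areas within 2%", {
  set.seed(42)
  for (i in 1:8) {
    r <- runif(1, 5, 18)
    a <- runif(1, 0.6, 1.4)
    circ <- circle_contour(25, 25, r, n = 90)
    v <- circ$vertices
    v[, 2] <- 25 + (v[, 2] - 25) * a
    m <- contour_to_mask(contour(1, v), c(50, 50))
    if (sum(m) < 50) next
    cts <- mask_to_contour(m)
    m2 <- contour_to_mask(cts[[1]], c(50, 50))
    expect_lt(abs(sum(m2) - sum(m)) / sum(m), 0.02)
  }
})

test_that("zoom and slice interpolation preserve extent and intensity", {
  v16 <- volume3d(array(stats::rnorm(8 * 8 * 16), c(8, 8, 16)),
                  spacing = c(0.67, 0.67, 2))
  out <- interp_slices(v16, 2 / 12)
  expect_equal(dim(out$data)[3], 192)
  expect_equal(out$spacing[3], 2 / 12)

  g <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
             function(a, b) sin(3 * a) + cos(2 * b))
  vol <- volume3d(array(rep(g, 2), c(32, 32, 2)))
  z <- zoom_inplane(vol, 4)
  expect_equal(dim(z$data)[1:2], c(128, 128))
  expect_lt(abs(mean(z$data) - mean(vol$data)) / abs(mean(vol$data)), 0.01)

  expect_identical(zoom_inplane(vol, 1), vol)
  const <- volume3d(array(7, c(16, 16, 2)))
  expect_lt(max(abs(zoom_inplane(const, 3)$data - 7)), 1e-9)
  expect_error(zoom_inplane(vol, 0.5), "factor")
})

test_that("zoom then unzoom of a smooth phantom has < 1% NRMS error", {
  g <- outer(seq(0, 2, length.out = 48), seq(0, 2, length.out = 48),
             function(a, b) 100 + 40 * sin(2 * a) * cos(1.5 * b))
  vol <- volume3d(array(g, c(48, 48, 1)))
  z <- zoom_inplane(vol, 4)
  back <- template_down2 <- z$data[, , 1]
  # un-zoom by 4x block averaging
  idx <- function(k) seq(k, 192, by = 4)
  back <- (back[idx(1), ] + back[idx(2), ] + back[idx(3), ] + back[idx(4), ]) / 4
  back <- (back[, idx(1)] + back[, idx(2)] + back[, idx(3)] + back[, idx(4)]) / 4
  nrmse <- sqrt(mean((back - g)^2)) / diff(range(g))
  expect_lt(nrmse, 0.01)
})

test_that("structure set JSON round trip and invariants", {
  s <- structure_set(list(
    contour(3, circle_contour(10, 10, 4)$vertices, label = "RN",
            hemisphere = "L"),
    contour(4, circle_contour(10, 10, 4.5)$vertices, label = "RN",
            hemisphere = "L"),
    contour(3, rbind(c(20, 20), c(28, 20), c(28, 26), c(20, 26)),
            label = "BG", hemisphere = "R")))
  f <- tempfile(fileext = ".json")
  write_structures(s, f)
  r <- read_structures(f)
  expect_length(r, 3)
  expect_equal(r$contours[[1]]$vertices, s$contours[[1]]$vertices)
  expect_equal(vapply(r$contours, `[[`, character(1), "label"),
               c("RN", "RN", "BG"))
  expect_silent(validate_structures(r, grid_dim = c(40, 40)))

  dup <- structure_set(list(s$contours[[1]], s$contours[[1]]))
  expect_error(validate_structures(dup), "duplicated")
})

test_that("rasterized label masks reproduce contour areas", {
  s <- structure_set(list(
    contour(1, circle_contour(15, 15, 6)$vertices, label = "RN"),
    contour(2, circle_contour(20, 20, 8)$vertices, label = "SN")))
  ras <- rasterize_structures(s, c(40, 40, 2))
  m1 <- contour_to_mask(s$contours[[1]], c(40, 40))
  expect_equal(sum(ras$volume$data[, , 1] == ras$legend[["RN"]]), sum(m1))
})
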