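cfg <- qsm_config()

test_that("dipole kernel matches its closed form and the magic angle", {
  D <- dipole_kernel(c(16, 16, 16))
  expect_equal(D[1, 1, 2], -2 / 3)          # k along B0
  expect_equal(D[2, 1, 1], 1 / 3)           # k perpendicular to B0
  expect_equal(D[1, 1, 1], 0)
  expect_error(dipole_kernel(c(16, 16, 16), B0_dir = c(0, 0, 0)), "B0")
  expect_error(dipole_kernel(c(4, 16, 16)), "8")

  # field of a uniform sphere vanishes near the magic angle (54.7 deg):
  # compare cone points against the on-axis field at the same radius
  n <- 64
  chi <- sphere_chi(c(n, n, n), rep(n / 2 + 0.5, 3), 6, 100)
  fld <- forward_field(chi)
  ctr <- n / 2 + 0.5
  thm <- acos(1 / sqrt(3))
  rr <- 14
  az <- seq(0, 2 * pi, length.out = 9)[-9]
  cone <- cbind(round(ctr + rr * sin(thm) * cos(az)),
                round(ctr + rr * sin(thm) * sin(az)),
                round(ctr + rr * cos(thm)))
  pole <- abs(fld[round(ctr), round(ctr), round(ctr + rr)])
  expect_lt(mean(abs(fld[cone])), 0.15 * pole)
})

test_that("phase unwrapping recovers a wrapped ramp congruently", {
  d <- c(32, 32, 8)
  ramp <- array(rep(seq(0, 6 * pi, length.out = d[1]), times = d[2] * d[3]), d)
  wr <- atan2(sin(ramp), cos(ramp))
  mask <- array(TRUE, d)
  uw <- unwrap_phase(wr, mask)
  off <- (uw - ramp) / (2 * pi)
  expect_lt(max(abs(off - off[1])), 1e-8)                 # global 2*pi*k only
  expect_equal(off[1], round(off[1]))
  resid <- atan2(sin(uw - wr), cos(uw - wr))
  expect_lt(max(abs(resid)), 1e-8)                        # congruence

  sm <- array(0.5 * sin(seq(0, pi, length.out = d[1])), d)
  expect_equal(unwrap_phase(sm, mask), sm)                # already unwrapped

  m2 <- mask; m2[, , 5:8] <- FALSE
  uw2 <- unwrap_phase(wr, m2)
  expect_identical(uw2[, , 5:8], wr[, , 5:8])             # untouched outside
  expect_error(unwrap_phase(wr, array(FALSE, d)), "mask")
})

test_that("SHARP removes external-source fields and keeps internal ones", {
  n <- 64
  ctr <- n / 2 + 0.5
  r2 <- array(0, c(n, n, n))
  for (k in 1:n) r2[, , k] <- outer((1:n - ctr)^2, (1:n - ctr)^2, `+`) +
      (k - ctr)^2
  mask <- r2 <= 16^2
  ext <- sphere_chi(c(n, n, n), c(ctr, ctr, ctr + 16 + 12), 3, 1e4)
  f_ext <- forward_field(ext)
  sh <- sharp_filter(f_ext, mask, cfg)
  supp <- sqrt(mean(sh$field[sh$mask_eroded]^2)) /
    sqrt(mean(f_ext[sh$mask_eroded]^2))
  expect_lt(supp, 0.05)

  int <- sphere_chi(c(n, n, n), rep(ctr, 3), 4, 100)
  f_int <- forward_field(int)
  sh2 <- sharp_filter(f_int, mask, cfg)
  rel <- sqrt(mean((sh2$field[sh2$mask_eroded] - f_int[sh2$mask_eroded])^2)) /
    sqrt(mean(f_int[sh2$mask_eroded]^2))
  expect_lt(rel, 0.10)

  z <- sharp_filter(array(0, c(n, n, n)), mask, cfg)
  expect_equal(max(abs(z$field)), 0)

  thin <- array(FALSE, c(n, n, n)); thin[30:34, , ] <- TRUE
  expect_error(sharp_filter(f_int, thin, cfg), "erode")
})

test_that("TKD inversion recovers a sphere and is linear", {
  n <- 64
  chi <- sphere_chi(c(n, n, n), rep(n / 2 + 0.5, 3), 6, 100)
  fld <- forward_field(chi) * midbrainseg:::phase_scale(cfg)
  mask <- array(TRUE, c(n, n, n))
  rec <- tkd_invert(fld, mask, cfg)
  expect_lt(abs(mean(rec$data[chi > 0]) - 100) / 100, 0.25)
  expect_equal(max(abs(tkd_invert(array(0, c(n, n, n)), mask, cfg)$data)), 0)
  rec2 <- tkd_invert(2 * fld, mask, cfg)
  expect_equal(rec2$data, 2 * rec$data, tolerance = 1e-10)
})

test_that("iterative TKD beats plain TKD on the sphere phantom", {
  n <- 64
  chi <- sphere_chi(c(n, n, n), rep(n / 2 + 0.5, 3), 6, 100)
  fld <- forward_field(chi) * midbrainseg:::phase_scale(cfg)
  mask <- array(TRUE, c(n, n, n))
  plain <- tkd_invert(fld, mask, cfg)
  iter <- iterative_tkd(fld, mask, cfg)
  err_plain <- abs(mean(plain$data[chi > 0]) - 100)
  err_iter <- abs(mean(iter$data[chi > 0]) - 100)
  expect_lte(err_iter, err_plain + 1e-9)
  # streaking energy outside the sphere is not larger
  expect_lte(stats::var(iter$data[chi == 0]), stats::var(plain$data[chi == 0]))

  expect_error(iterative_tkd(fld, mask, qsm_config(n_iterations = 0)),
               "n_iterations")
  expect_equal(max(abs(iterative_tkd(array(0, c(n, n, n)), mask, cfg)$data)), 0)
})

test_that("full chain on a two-sphere phantom preserves ordering and ratio", {
  n <- 64
  ctr <- n / 2 + 0.5
  chi <- sphere_chi(c(n, n, n), c(ctr - 10, ctr, ctr), 5, 50) +
    sphere_chi(c(n, n, n), c(ctr + 10, ctr, ctr), 5, 150)
  ph <- make_qsm_phantom(grid = c(n, n, n),
                         spheres = list(
                           list(center = c(ctr - 10, ctr, ctr), radius = 5,
                                chi_ppb = 50),
                           list(center = c(ctr + 10, ctr, ctr), radius = 5,
                                chi_ppb = 150)),
                         mask_radius = 22)
  rec <- qsm_reconstruct(ph$phase$data, ph$mask, cfg)
  m1 <- ph$chi_truth == 50 & rec$mask_eroded
  m2 <- ph$chi_truth == 150 & rec$mask_eroded
  mu1 <- mean(rec$chi$data[m1]); mu2 <- mean(rec$chi$data[m2])
  expect_gt(mu2, mu1)
  expect_lt(abs(mu2 / mu1 - 3) / 3, 0.20)
  expect_equal(max(abs(rec$chi$data[!rec$mask_eroded])), 0)
  expect_false(any(!is.finite(rec$chi$data)))
})
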