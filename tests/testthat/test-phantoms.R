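test_that("shape phantoms hit their canonical areas and CNR", {
  p <- make_shape_phantom("rectangle", cnr = Inf)
  expect_equal(sum(p$truth), 1400)            # 35 x 40

  a <- make_shape_phantom("moon", cnr = 7, seed = 2)
  b <- make_shape_phantom("moon", cnr = 7, seed = 2)
  expect_identical(a$image, b$image)           # deterministic
  c2 <- make_shape_phantom("moon", cnr = 7, seed = 3)
  expect_false(identical(a$image, c2$image))

  cnr_hat <- (mean(a$image[a$truth]) - mean(a$image[!a$truth])) /
    stats::sd(a$image[!a$truth])
  expect_gt(cnr_hat, 6.5); expect_lt(cnr_hat, 7.5)

  expect_error(make_shape_phantom("disk", canvas = c(30, 30), size = 20),
               "canvas")
})

test_that("midbrain phantom truth satisfies the anatomical invariants", {
  ph <- make_midbrain_phantom(seed = 1, warp = FALSE)
  d <- dim(ph$chi$data)
  sn <- structures_mask(ph$truth, d, label = "SN")
  rn <- structures_mask(ph$truth, d, label = "RN")
  stn <- structures_mask(ph$truth, d, label = "STN")
  nm <- structures_mask(ph$truth, d, label = "NM")
  vta <- structures_mask(ph$truth, d, label = "VTA")
  expect_equal(sum(sn & rn), 0)
  expect_equal(sum(sn & stn), 0)
  expect_equal(sum(rn & stn), 0)
  expect_gt(sum(vta & nm) / sum(vta), 0.97)    # VTA sits inside the NM blob
  expect_gt(sum(nm & sn), 100)                 # an SNpc overlap exists
  expect_silent(validate_structures(ph$truth, grid_dim = d[1:2]))

  # susceptibility levels near their nominal means
  expect_lt(abs(mean(ph$chi$data[sn]) - 125), 10)
  expect_lt(abs(mean(ph$chi$data[rn]) - 100), 10)
  # NM contrast within the 5-10% band over the 1000 a.u. background
  expect_gt(ph$contrast_pct, 5); expect_lt(ph$contrast_pct, 10)
})

test_that("warped subjects are deterministic with bounded volume spread", {
  a <- make_midbrain_phantom(seed = 5)
  b <- make_midbrain_phantom(seed = 5)
  expect_identical(a$nm$data, b$nm$data)
  d <- dim(a$chi$data)
  vols <- vapply(1:10, function(s)
    sum(structures_mask(make_midbrain_phantom(seed = s)$truth, d,
                        label = "SN")), numeric(1))
  expect_lt((max(vols) - min(vols)) / mean(vols), 0.3)  # ~ +/-15% about nominal

  g <- make_midbrain_phantom(seed = 2, nigrosome_gap = TRUE)
  ng <- make_midbrain_phantom(seed = 2, nigrosome_gap = FALSE)
  sn <- structures_mask(g$truth, d, label = "SN")
  expect_lt(mean(g$chi$data[sn]), mean(ng$chi$data[sn]))  # interior notch
})

test_that("the constructed pars compacta equals its definition on truth masks", {
  ph <- make_midbrain_phantom(seed = 3, warp = FALSE)
  d <- dim(ph$chi$data)
  nm <- structures_mask(ph$truth, d, label = "NM")
  sn <- structures_mask(ph$truth, d, label = "SN")
  vta <- structures_mask(ph$truth, d, label = "VTA")
  snpc <- derive_snpc(nm, sn, vta)
  expect_identical(snpc, nm & !vta & sn)
  expect_gt(sum(snpc), 0)
})

test_that("dipole-forward phantom matches the analytic sphere field", {
  ph <- make_qsm_phantom(grid = c(64, 64, 64))
  expect_equal(max(abs(make_qsm_phantom(spheres = list(
    list(center = c(32, 32, 32), radius = 5, chi_ppb = 0)))$phase$data)), 0)

  # single-voxel source: field proportional to the discrete dipole response
  imp <- array(0, c(16, 16, 16)); imp[9, 9, 9] <- 1
  f1 <- forward_field(imp)
  f2 <- forward_field(2 * imp)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)

  # analytic external dipole field of a uniform sphere beyond 2 radii
  # (integer-centered so the sampling sits exactly on voxel centers)
  a <- 6; chi0 <- 100
  ctr <- 33L
  fld <- make_qsm_phantom(grid = c(64, 64, 64),
                          spheres = list(list(center = rep(ctr, 3),
                                              radius = a,
                                              chi_ppb = chi0)))$field_ppb
  pts <- expand.grid(dx = seq(-16, 16, 2), dy = seq(-16, 16, 2),
                     dz = seq(-16, 16, 2))
  rr <- sqrt(rowSums(pts^2))
  keep <- rr > 2 * a & rr < 16
  pts <- pts[keep, ]; rr <- rr[keep]
  costh <- pts$dz / rr
  analytic <- chi0 * a^3 / 3 * (3 * costh^2 - 1) / rr^3
  got <- fld[cbind(ctr + pts$dx, ctr + pts$dy, ctr + pts$dz)]
  rel <- sqrt(mean((got - analytic)^2)) / sqrt(mean(analytic^2))
  expect_lt(rel, 0.05)

  # phase wrapped into (-pi, pi]
  wp <- make_qsm_phantom(spheres = list(list(center = c(32, 32, 32),
                                             radius = 10, chi_ppb = 4000)))
  expect_lte(max(wp$phase$data), pi)
  expect_gt(max(wp$phase$data), pi / 2)   # genuinely wrapped input
})
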