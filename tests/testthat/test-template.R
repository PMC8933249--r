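test_that("red nucleus anchoring follows the two- and three-slice rules", {
  fix <- pipeline_fixture()
  bundle <- fix$bundle
  idtf <- spatial_transform(center = c(31.5, 31.5))
  sub <- fix$best$nm

  crop <- locate_crop(sub, idtf, bundle)
  # reference RN spans slices 31..33: middle slice anchored at crop slice 10
  expect_equal(crop$anchor, 32L)
  expect_equal(crop$slices[10], crop$anchor)

  # a half-slice shift makes the mapped RN span two slices: lower one anchors
  tf2 <- spatial_transform(center = c(31.5, 31.5), tz = 0.5)
  crop2 <- locate_crop(sub, tf2, bundle)
  expect_length(crop2$rn_slices, 3L)
  tf2b <- spatial_transform(center = c(31.5, 31.5), tz = 0.4)
  crop2b <- locate_crop(sub, tf2b, bundle)
  expect_equal(crop2b$anchor, crop2b$rn_slices[ceiling(length(crop2b$rn_slices) / 2)])

  # two-slice reference: lower slice becomes slice 10
  b2 <- bundle; b2$ref_rn <- c(32L, 33L)
  crop3 <- locate_crop(sub, idtf, b2)
  expect_equal(crop3$anchor, 32L)
  expect_equal(crop3$rn_slices, c(32L, 33L))

  # red nucleus too close to the top: localization error
  tf_top <- spatial_transform(center = c(31.5, 31.5), tz = 27)
  expect_error(locate_crop(sub, tf_top, bundle), "16-slice")
})

test_that("boundary mapping is exact under identity and translations", {
  fix <- pipeline_fixture()
  bundle <- fix$bundle
  idtf <- spatial_transform(center = c(127.5, 127.5),
                            dim_fixed = dim(bundle$nm_zoom$data))
  mapped <- map_boundaries_to_subject(bundle, idtf, bundle$crop_start)
  # pick an RN contour and compare with the template boundary it came from
  rn_t <- ss_filter(bundle$boundaries, label = "RN", hemisphere = "R")$contours
  rn_m <- ss_filter(mapped, label = "RN", hemisphere = "R")$contours
  expect_equal(length(rn_m), length(rn_t))
  a_t <- sort(vapply(rn_t, function(ct) polygon_area(ct$vertices) /
                       bundle$zoom^2, numeric(1)))
  a_m <- sort(vapply(rn_m, function(ct) polygon_area(ct$vertices), numeric(1)))
  # uniform arc-length resampling nudges vertices along edges: allow 0.5%
  expect_lt(max(abs(a_m - a_t) / a_t), 0.005)

  # pure 2 px in-plane translation (zoomed frame) moves every vertex by
  # exactly 0.5 original-resolution pixels
  tr <- spatial_transform(t2 = c(2, 0), center = c(127.5, 127.5),
                          dim_fixed = dim(bundle$nm_zoom$data))
  mapped2 <- map_boundaries_to_subject(bundle, tr, bundle$crop_start)
  v0 <- ss_filter(mapped, label = "RN", hemisphere = "R")$contours[[1]]$vertices
  v1 <- ss_filter(mapped2, label = "RN", hemisphere = "R")$contours[[1]]$vertices
  expect_equal(v1 - v0, matrix(rep(c(0.5, 0), each = nrow(v0)), ncol = 2),
               tolerance = 1e-8)
})

test_that("averaging identical subjects reproduces the template", {
  best <- make_midbrain_phantom(seed = 0, warp = FALSE)
  be <- registration_backend(demons_iter = 10L, affine_maxit = 150L)
  bundle <- build_template(list(best, best, best), backend = be,
                           finalize_dpa = FALSE)
  ref_crop <- zoom_inplane(volume3d(best$nm$data[, , 23:38],
                                    spacing = best$nm$spacing), 4)
  rel <- sqrt(mean((bundle$nm_zoom$data - ref_crop$data)^2)) /
    diff(range(ref_crop$data))
  expect_lt(rel, 0.01)
  expect_equal(bundle$n_subjects_averaged, 3L)

  expect_warning(build_template(list(best), backend = be,
                                finalize_dpa = FALSE), "single")
})

test_that("segmenting the template case against itself is near-perfect", {
  fix <- pipeline_fixture()
  seg <- segment_subject(fix$best$nm, fix$best$chi, fix$bundle,
                         backend = fix$backend)
  expect_length(seg$errors, 0)
  d <- dim(fix$best$nm$data)
  for (lab in c("NM", "SN", "RN", "STN")) {
    ma <- structures_mask(seg$structures, d, label = lab)
    mt <- structures_mask(fix$best$truth, d, label = lab)
    expect_gt(dice(ma, mt), 0.9)
  }
})

test_that("refined iron structures never overlap and QSM failure is isolated", {
  fix <- pipeline_fixture()
  sub <- make_midbrain_phantom(seed = 21)
  seg <- segment_subject(sub$nm, sub$chi, fix$bundle, backend = fix$backend)
  d <- dim(sub$nm$data)
  sn <- structures_mask(seg$structures, d, label = "SN")
  rn <- structures_mask(seg$structures, d, label = "RN")
  stn <- structures_mask(seg$structures, d, label = "STN")
  expect_equal(sum(sn & rn), 0)
  expect_equal(sum(sn & stn), 0)
  expect_equal(sum(rn & stn), 0)

  # an all-zero susceptibility map collapses SN/RN/STN but NM still segments
  chi0 <- volume3d(array(0, d), spacing = sub$chi$spacing)
  seg0 <- segment_subject(sub$nm, chi0, fix$bundle, backend = fix$backend)
  expect_gt(length(seg0$errors), 0)
  labs_err <- unique(sub("/.*", "", names(seg0$errors)))
  expect_true(all(labs_err %in% c("SN", "RN", "STN")))
  expect_gt(length(ss_filter(seg0$structures, label = "NM")$contours), 0)
})
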