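test_that("background statistics pool the BG ROI pixels", {
  img <- array(1000, c(40, 40, 2))
  bg <- structure_set(list(
    contour(1, rbind(c(4.5, 4.5), c(9.5, 4.5), c(9.5, 9.5), c(4.5, 9.5)),
            label = "BG"),
    contour(2, rbind(c(19.5, 19.5), c(24.5, 19.5), c(24.5, 24.5),
                     c(19.5, 24.5)), label = "BG")))
  st <- background_stats(img, bg)
  expect_equal(st$mean, 1000)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pixels, 50)

  # two boxes with different values: pooled mean/sd
  img2 <- img
  img2[6:10, 6:10, 1] <- 100
  img2[21:25, 21:25, 2] <- 200
  st2 <- background_stats(img2, bg)
  expect_equal(st2$mean, 150)
  expect_equal(st2$sd, stats::sd(c(rep(100, 25), rep(200, 25))))

  tiny <- structure_set(list(
    contour(1, rbind(c(4.6, 4.6), c(7.4, 4.6), c(7.4, 7.4), c(4.6, 7.4)),
            label = "BG")))
  expect_error(background_stats(img, tiny), "small")
  expect_error(background_stats(img, structure_set()), "BG")
})

test_that("the NM floor is mean + multiplier * SD and separates a blob", {
  bg <- structure(list(mean = 1000, sd = 30, n_pixels = 100),
                  class = "background_stats")
  expect_equal(nm_floor(bg, threshold_config(), sd_ref = 25), 1100)
  expect_equal(nm_floor(bg, threshold_config(nm_sd_multiplier = 0)), 1000)
  expect_equal(nm_floor(bg, threshold_config()), 1120)   # per-subject fallback

  # +8% blob over bg with 1% noise: blob survives, background zeroed
  set.seed(3)
  img <- matrix(rnorm(10000, 1000, 10), 100, 100)
  img[40:60, 40:60] <- rnorm(441, 1080, 10)
  flo <- nm_floor(structure(list(mean = 1000, sd = 10, n_pixels = 400),
                            class = "background_stats"), threshold_config())
  blob <- img[40:60, 40:60]
  bgpx <- img[1:30, 1:30]
  expect_gt(mean(blob >= flo), 0.99)        # Phi(4) tail on the blob side
  expect_gt(mean(bgpx < flo), 0.9999 - 3 / length(bgpx))
})

test_that("Otsu threshold equals the exhaustive within-class scan", {
  v <- c(rep(0, 100), rep(10, 100))
  t0 <- otsu_threshold(v)
  expect_gt(t0, 0); expect_lt(t0, 10)

  # exhaustive intra-class variance oracle on random bimodal histograms
  set.seed(21)
  for (i in 1:50) {
    mu1 <- runif(1, 0, 40)
    mu <- c(mu1, mu1 + runif(1, 30, 60))
    sd <- runif(2, 2, 6)
    v <- c(rnorm(1000, mu[1], sd[1]), rnorm(1000, mu[2], sd[2]))
    br <- seq(min(v), max(v), length.out = 257)
    wcv <- sapply(2:256, function(k) {
      thr <- br[k]
      lo <- v[v < thr]; hi <- v[v >= thr]
      if (!length(lo) || !length(hi)) return(Inf)
      sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    })
    got_k <- findInterval(otsu_threshold(v), br, rightmost.closed = TRUE)
    # attains the exhaustive minimum (gap thresholds are equivalent)
    expect_lte(wcv[got_k - 1L] - min(wcv),
               1e-3 * (stats::median(wcv) - min(wcv)))
  }

  expect_error(otsu_threshold(rep(5, 100)), "constant")
})

test_that("QSM preparation applies the negativity rule and the 30 ppb cap", {
  chi <- matrix(0, 60, 60)
  chi[20:40, 20:40] <- 120
  roi <- circle_contour(29.5, 29.5, 14)
  qp <- qsm_prepare(chi, roi, threshold_config())
  expect_lte(qp$threshold, 30)            # capped even if Otsu is larger
  expect_gte(qp$otsu, 30)

  # all-positive uniform ROI: degenerate Otsu handled as a no-op
  chi2 <- matrix(100, 60, 60)
  qp2 <- qsm_prepare(chi2, roi, threshold_config())
  expect_true(is.na(qp2$otsu))
  expect_equal(qp2$map, chi2)

  # negative rim is zeroed before the Otsu analysis
  chi3 <- chi
  chi3[18:19, 18:42] <- -50
  roi3 <- circle_contour(29.5, 29.5, 16)
  qp3 <- qsm_prepare(chi3, roi3, threshold_config())
  expect_equal(sum(qp3$map < 0 & contour_to_mask(roi3, c(60, 60))), 0)

  # never increases the ROI
  m0 <- contour_to_mask(roi, c(60, 60))
  expect_true(all(m0[qp$mask]))

  expect_error(qsm_prepare(matrix(-5, 60, 60), roi, threshold_config()),
               "negative")
})

test_that("gating reports step-logic volume loss and Gaussian tails", {
  m <- matrix(TRUE, 50, 50)
  map <- matrix(6, 50, 50)   # uniform +6% contrast
  expect_equal(gate_structure(map, m, 0)$volume_loss, 0)
  expect_equal(gate_structure(map, m, 5)$volume_loss, 0)
  expect_equal(gate_structure(map, m, 7)$volume_loss, 1)

  set.seed(14)
  chi <- matrix(rnorm(5000, 125, 30), 100, 50)
  mm <- matrix(TRUE, 100, 50)
  gs <- gate_structure(chi, mm, 50)
  expect_lt(abs(gs$volume_loss - stats::pnorm(50, 125, 30)), 0.02)
})

test_that("volume loss is non-decreasing in the gate", {
  set.seed(4)
  map <- matrix(rnorm(2500, 60, 40), 50, 50)
  m <- matrix(runif(2500) < 0.7, 50, 50)
  losses <- sapply(c(0, 25, 50, 75, 100), function(g)
    gate_structure(map, m, g)$volume_loss)
  expect_true(all(diff(losses) >= 0))
})

test_that("NM contrast is percent over the background mean", {
  bg <- structure(list(mean = 1000, sd = 10, n_pixels = 50),
                  class = "background_stats")
  expect_equal(nm_contrast(1050, bg), 5)
  expect_equal(nm_contrast(1000, bg), 0)
})
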