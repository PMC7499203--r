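# ROI detection: smoothing, mask geometry, watershed segmentation,
# ROI placement, mode background.

test_that("3x3 Gaussian smoothing preserves constants, mass and spot argmax", {
  const <- matrix(7.5, 20, 20)
  expect_equal(smooth_gauss3(const), const)

  # single bright pixel: kernel weights spread its mass but conserve it
  img <- matrix(0, 11, 11); img[6, 6] <- 16
  sm <- smooth_gauss3(img)
  expect_equal(sum(sm), 16)
  expect_equal(sm[6, 6], 4)       # center weight 4/16 of mass 16
  expect_equal(sm[5, 6], 2)       # edge-adjacent weight 2/16
  expect_equal(sm[5, 5], 1)       # corner weight 1/16
  expect_equal(sum(sm[5:7, 5:7]), 16)

  # a Gaussian spot's argmax is unchanged by smoothing (brute force)
  g <- outer(1:21, 1:21, function(r, c) 80 * exp(-((r - 13)^2 + (c - 9)^2) / 2))
  expect_equal(which.max(smooth_gauss3(g)), which.max(g))

  expect_error(smooth_gauss3(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("ROI mask is the 13-pixel disc of radius 2", {
  offs <- roi_mask_offsets()
  # independent enumeration oracle
  oracle <- NULL
  for (dr in -2:2) for (dc in -2:2)
    if (dr^2 + dc^2 <= 4) oracle <- rbind(oracle, c(dr, dc))
  expect_equal(nrow(offs), 13L)
  expect_equal(nrow(oracle), 13L)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(offs), key(oracle))
})

test_that("image mode takes the smallest most-frequent DN value", {
  expect_equal(image_mode(matrix(10, 5, 5)), 10)
  m <- matrix(c(rep(3, 10), rep(9, 10), rep(4, 5)), ncol = 5)
  expect_equal(image_mode(m), 3)  # tie between 3 and 9 -> smaller
  expect_equal(image_mode(matrix(c(2.4, 2.4, 7.9), 1)), 2)  # binned at 1 DN
})

test_that("watershed separates well-separated spots and rejects large/small segments", {
  mk_spot_img <- function(centers, amp = 100, bg = 10, n = 32) {
    img <- matrix(bg, n, n)
    for (i in seq_len(nrow(centers)))
      img <- img + amp * outer(1:n, 1:n, function(r, c)
        exp(-((r - centers[i, 1])^2 + (c - centers[i, 2])^2) / 2))
    img
  }
  centers <- rbind(c(9, 9), c(24, 22))
  sm <- smooth_gauss3(mk_spot_img(centers))
  lab <- segment_watershed(sm, detection_params())
  expect_equal(max(lab), 2L)
  # each segment contains one spot center; oracle: connected components
  # of the thresholded image found by BFS
  thr <- stats::quantile(sm, 0.9, names = FALSE)
  cc <- local({
    seen <- matrix(FALSE, 32, 32); comp <- 0
    for (r0 in 1:32) for (c0 in 1:32) {
      if (sm[r0, c0] <= thr || seen[r0, c0]) next
      comp <- comp + 1
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r < 1 || r > 32 || c < 1 || c > 32) next
          if (!seen[r, c] && sm[r, c] > thr) {
            seen[r, c] <- TRUE; queue <- c(queue, list(c(r, c)))
          }
        }
      }
    }
    comp
  })
  expect_equal(max(lab), cc)
  expect_true(lab[9, 9] > 0 && lab[24, 22] > 0)
  expect_true(lab[9, 9] != lab[24, 22])

  # constant image: no maxima above threshold
  expect_warning(lab0 <- segment_watershed(matrix(5, 16, 16)), "no maxima")
  expect_equal(max(lab0), 0L)

  # a big plateau (soma-like disc) is rejected by the area cap
  img <- matrix(10, 64, 64)
  img[22:41, 22:41] <- 500   # 400 px plateau > max_segment_area
  lab <- segment_watershed(smooth_gauss3(img), detection_params())
  expect_equal(max(lab), 0L)

  # retained labels are disjoint by construction (label matrix property)
  f <- generate_field(sim_params(seed = 5))
  sm <- smooth_gauss3(f$image$channels$red)
  lab <- segment_watershed(sm)
  area <- tabulate(lab[lab > 0])
  expect_true(all(area >= 3 & area <= 200))
})

test_that("place_rois centers ROIs on segment maxima and measures raw means", {
  # one synthetic segment with known max position
  img <- matrix(10, 20, 20)
  img[10, 10] <- 100; img[10, 11] <- 60
  lab <- matrix(0L, 20, 20); lab[8:12, 8:13] <- 1L
  fi <- make_field(img)
  tab <- place_rois(lab, img, fi, detection_params())
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$row, tab$col), c(10, 10))
  # hand-computed 13-pixel raw mean: 12 pixels at 10 except the two bright
  offs <- roi_mask_offsets()
  vals <- img[cbind(10 + offs[, 1], 10 + offs[, 2])]
  expect_equal(tab$mean_red, mean(vals))
  expect_equal(tab$mean_red, (100 + 60 + 11 * 10) / 13)

  # ROI whose mask would cross the border is dropped
  lab2 <- matrix(0L, 20, 20); lab2[1:3, 1:3] <- 1L
  img2 <- matrix(10, 20, 20); img2[2, 2] <- 50
  expect_equal(nrow(place_rois(lab2, img2, make_field(img2), detection_params())), 0L)

  # tie-break: two equal maxima -> smallest row, then column
  img3 <- matrix(0, 20, 20); lab3 <- matrix(0L, 20, 20)
  lab3[5:9, 5:9] <- 1L
  img3[6, 8] <- 77; img3[8, 6] <- 77
  tab3 <- place_rois(lab3, img3, make_field(img3), detection_params())
  expect_equal(c(tab3$row, tab3$col), c(6, 8))

  expect_error(place_rois(matrix(0L, 5, 5), img, fi), "shapes differ")
})

test_that("noiseless spot ROI mean matches the analytic profile mean", {
  p <- noiseless_params(n_spines = 0, n_shafts = 0, n_somata = 0)
  amp <- 240; sigma <- p$spot_sigma
  img <- matrix(p$background_level, 64, 64)
  img <- img + amp * outer(1:64, 1:64, function(r, c) {
    d2 <- (r - 30)^2 + (c - 33)^2
    ifelse(d2 <= (4 * sigma)^2, exp(-d2 / (2 * sigma^2)), 0)
  })
  tab <- detect_rois(make_field(img))
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$row, tab$col), c(30, 33))
  # closed-form expectation, enumerated independently of roi_mask_offsets
  acc <- 0; npx <- 0
  for (dr in -2:2) for (dc in -2:2) if (dr^2 + dc^2 <= 4) {
    acc <- acc + amp * exp(-(dr^2 + dc^2) / (2 * sigma^2)); npx <- npx + 1
  }
  expect_equal(tab$mean_red, p$background_level + acc / npx, tolerance = 1e-12)
})

test_that("background is the lesser hemisphere mode and is accurate under noise", {
  a <- make_field(matrix(10, 16, 16)); b <- make_field(matrix(10, 16, 16))
  expect_equal(estimate_background(a, b, "red"), 10)
  b2 <- make_field(matrix(12, 16, 16))
  expect_equal(estimate_background(a, b2, "red"), 10)
  expect_error(estimate_background(a, b, "actinin"), "missing")

  # Monte-Carlo: pedestal 100, read noise sd 2, default fields
  est <- vapply(1:100, function(s) {
    L <- generate_field(sim_params(seed = 4000 + s, read_noise_sd = 2))$image
    R <- generate_field(sim_params(seed = 8000 + s, read_noise_sd = 2))$image
    estimate_background(L, R, "red")
  }, numeric(1))
  expect_true(abs(mean(est) - 100) <= 1)
  expect_true(all(abs(est - 100) <= 2))
})

test_that("set_background validates channels and detect_rois counts match segments", {
  f <- generate_field(sim_params(seed = 3))
  sm <- smooth_gauss3(f$image$channels$red)
  lab <- segment_watershed(sm)
  tab <- place_rois(lab, sm, f$image)
  expect_lte(nrow(tab), max(lab))
  expect_true(!any(duplicated(tab[, c("row", "col")])))
  expect_error(set_background(tab, c(red = 100)), "missing")
  expect_error(set_background(tab, c(red = -1, green = 5)), ">= 0")
  tb <- set_background(tab, c(red = 100, green = 100))
  expect_equal(unique(tb$bg_red), 100)
})
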