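test_that("two distant points give K = L = 0 below their separation", {
  pts <- tibble::tibble(x = c(5000, 5400), y = c(5000, 5000))
  res <- suppressWarnings(
    ripley_k_l(pts, window_rect(0, 1e4, 0, 1e4), r_max = 300))
  expect_true(all(res$k == 0))
  expect_true(all(res$l == 0))
  expect_error(ripley_k_l(pts[1, ], window_rect(0, 1e4, 0, 1e4)), "at least 2")
  expect_error(suppressWarnings(ripley_k_l(pts, window_rect(0, 1e4, 0, 1e4),
                                           r_max = -5)), "positive")
})

test_that("deep-interior patterns reproduce the naive O(n^2) oracle exactly", {
  set.seed(21)
  # all points > r_max from every edge: every e_ij must equal 1 exactly
  pts <- tibble::tibble(x = runif(80, 4000, 6000), y = runif(80, 4000, 6000))
  w <- window_rect(0, 1e4, 0, 1e4)
  rg <- seq(100, 1000, by = 100)
  res <- ripley_k_l(pts, w, r_max = 1000, r_grid = rg)
  expect_equal(res$k, naive_k(pts, window_area(w), rg), tolerance = 1e-12)
  expect_equal(attr(res, "max_weight"), 1)
  # same equivalence through the polygonal-window code path
  wp <- window_poly(cbind(c(0, 1e4, 1e4, 0), c(0, 0, 1e4, 1e4)))
  resp <- ripley_k_l(pts, wp, r_max = 1000, r_grid = rg)
  expect_equal(resp$k, naive_k(pts, window_area(w), rg), tolerance = 1e-12)
})

test_that("rectangle and sampled-polygon corrections agree near the boundary", {
  set.seed(4)
  w <- window_rect(0, 1000, 0, 700)
  pts <- runif_in_window(60, w)
  r1 <- ripley_k_l(pts, w, r_max = 300)
  r2 <- ripley_k_l(pts, window_poly(cbind(c(0, 1000, 1000, 0), c(0, 0, 700, 700))),
                   r_max = 300, n_arc = 2880)
  expect_lt(max(abs(r1$k - r2$k) / pmax(r2$k, 1e-9)), 2e-3)
})

test_that("K is non-decreasing, L(0+) -> 0, and weights are >= 1", {
  for (s in 1:5) {
    set.seed(s)
    w <- window_rect(0, 2000, 0, 1500)
    pts <- runif_in_window(50, w)
    res <- ripley_k_l(pts, w, r_max = 700)
    expect_true(all(diff(res$k) >= 0))
    expect_gte(attr(res, "max_weight"), 1)
    expect_lt(res$l[1], 50)  # first grid point carries few pairs
  }
})

test_that("rigid motions of points and window leave K unchanged", {
  set.seed(12)
  w <- window_rect(0, 1000, 0, 600)
  pts <- runif_in_window(40, w)
  base <- ripley_k_l(pts, w, r_max = 200)
  shifted <- ripley_k_l(dplyr::mutate(pts, x = x + 3210.5, y = y - 87.25),
                        window_rect(3210.5, 4210.5, -87.25, 512.75), r_max = 200)
  expect_equal(shifted$k, base$k, tolerance = 1e-12)
  rotated <- ripley_k_l(tibble::tibble(x = pts$y, y = -pts$x),
                        window_rect(0, 600, -1000, 0), r_max = 200)
  expect_equal(rotated$k, base$k, tolerance = 1e-12)
  # polygon path: translation is exact too
  wp <- cbind(c(0, 1000, 500), c(0, 0, 600))
  tri_pts <- tibble::tibble(x = c(300, 400, 500, 350), y = c(100, 150, 120, 80))
  b2 <- suppressWarnings(ripley_k_l(tri_pts, window_poly(wp), r_max = 200))
  s2 <- suppressWarnings(
    ripley_k_l(dplyr::mutate(tri_pts, x = x + 5e4),
               window_poly(cbind(wp[, 1] + 5e4, wp[, 2])), r_max = 200))
  expect_equal(s2$k, b2$k, tolerance = 1e-12)
})

test_that("duplicate coordinates contribute at every radius", {
  pts <- tibble::tibble(x = c(500, 500, 900), y = c(500, 500, 500))
  res <- suppressWarnings(ripley_k_l(pts, window_rect(0, 1000, 0, 1000),
                                     r_max = 100))
  # the coincident pair (d = 0, weight 1 each way) is in every sum
  expect_true(all(res$k >= 1e6 / (3 * 2) * 2))
})

test_that("under CSR the corrected estimator is unbiased within Monte-Carlo error", {
  set.seed(99)
  w <- window_rect(0, 1, 0, 1)
  rg <- seq(0.05, 0.25, by = 0.05)
  km <- replicate(60, ripley_k_l(runif_in_window(100, w), w,
                                 r_max = 0.25, r_grid = rg)$k)
  z <- (rowMeans(km) - pi * rg^2) / (apply(km, 1, sd) / sqrt(60))
  expect_true(all(abs(z) < 4))
})

test_that("points outside the window are rejected", {
  pts <- tibble::tibble(x = c(10, 2000), y = c(10, 20))
  expect_error(suppressWarnings(ripley_k_l(pts, window_rect(0, 1000, 0, 1000))),
               "inside")
})

test_that("ROI filtering is boundary inclusive and binomial on half coverage", {
  r <- roi(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  pts <- tibble::tibble(x_nm = c(500, 0, 1000, 1500), y_nm = c(500, 0, 500, 500))
  kept <- points_in_roi(pts, r)
  expect_equal(nrow(kept), 3)  # centroid, vertex, edge in; outside point dropped
  set.seed(33)
  unif <- tibble::tibble(x_nm = runif(1e4, 0, 2000), y_nm = runif(1e4, 0, 1000))
  frac <- nrow(points_in_roi(unif, r)) / 1e4
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("ROI density, image density and their ratio are exact quotients", {
  r2 <- roi(c(0, 2000, 2000, 0), c(0, 0, 1000, 1000), id = "b", compartment = "bouton")
  empty <- tibble::tibble(x_nm = numeric(0), y_nm = numeric(0))
  expect_warning(d0 <- roi_density(empty, r2, c(0, 2000, 0, 1000)), "undefined")
  expect_equal(d0$density, 0)
  expect_true(is.na(d0$normalized_density))
  set.seed(2)
  inroi <- tibble::tibble(x_nm = runif(50, 0, 2000), y_nm = runif(50, 0, 1000))
  out <- roi_density(inroi, r2, c(0, 4000, 0, 1000))
  expect_equal(out$area_um2, 2)
  expect_equal(out$density, 25)          # 50 points in 2 um^2
  expect_equal(out$image_density, 12.5)  # 50 points over 4 um^2
  expect_equal(out$normalized_density, 2)
  # duplicating every point doubles both densities, ratio unchanged
  dup <- dplyr::bind_rows(inroi, inroi)
  out2 <- roi_density(dup, r2, c(0, 4000, 0, 1000))
  expect_equal(out2$density, 50)
  expect_equal(out2$normalized_density, out$normalized_density)
})

test_that("pooling far-apart ROIs preserves within-ROI structure only", {
  set.seed(6)
  mk <- function(seed) {
    w <- window_rect(0, 1500, 0, 1500)
    list(points = sim_localizations(point_process_config(w, "CSR", 40, seed = seed)),
         window = w)
  }
  single <- mk(1)
  pooled1 <- pool_rois(list(single), r_max = 1000)
  res_single <- ripley_k_l(single$points, single$window, r_max = 500)
  res_pooled1 <- ripley_k_l(pooled1$points, pooled1$window, r_max = 500)
  expect_equal(res_pooled1$k, res_single$k, tolerance = 0.02)  # arc sampling vs exact
  pooled <- pool_rois(list(mk(1), mk(2), mk(3)), r_max = 1000)
  expect_gt(pooled$min_separation, 1000)
  # constructive guarantee: no inter-set pair within r_max
  d <- as.matrix(dist(cbind(pooled$points$x, pooled$points$y)))
  cross <- outer(pooled$points$set, pooled$points$set, `!=`)
  expect_true(all(d[cross] > 1000))
  res <- ripley_k_l(pooled$points, pooled$window, r_max = 500)
  expect_true(all(diff(res$k) >= 0))
  expect_error(pool_rois(list()), "at least one")
})

test_that("CSR envelopes contain CSR and are escaped by tight Thomas clusters", {
  w <- window_rect(0, 2000, 0, 2000)
  env <- csr_envelope(w, n_points = 100, n_sims = 99, r_max = 500, n_r = 20,
                      seed = 14)
  obs <- ripley_k_l(runif_in_window(100, w), w, r_max = 500, n_r = 20)
  inside <- (obs$l - obs$r) >= env$lo & (obs$l - obs$r) <= env$hi
  expect_gte(mean(inside), 0.95)
  # a clustered pattern exceeds the upper envelope at short range
  th <- sim_localizations(point_process_config(w, "Thomas", 4,
                                               offspring_mean = 20,
                                               offspring_sigma = 30, seed = 3))
  env_th <- csr_envelope(w, n_points = nrow(th), n_sims = 99, r_max = 500,
                         n_r = 20, seed = 15)
  res_th <- ripley_k_l(th, w, r_max = 500, n_r = 20)
  short <- which(res_th$r <= 150)
  expect_true(any((res_th$l - res_th$r)[short] > env_th$hi[short]))
  # empty envelope is permitted but flagged
  expect_warning(e0 <- csr_envelope(w, 50, n_sims = 0, r_max = 500, n_r = 5),
                 "empty")
  expect_true(all(is.na(e0$lo)))
  expect_identical(attr(e0, "n_sims"), 0L)
})
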