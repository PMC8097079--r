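# Spatial statistics: k-NND, density, t-test, excess fractions, aggregated
# force, and the matched CSR null machinery.

test_that("k-NND handles fixtures exactly and is monotone in k", {
  two <- data.frame(x = c(0, 10), y = c(0, 0))
  nnd <- knn_distances(two, k = 1)
  expect_equal(nnd$distance, c(10, 10))
  # 3x3 grid at 20 nm spacing
  g <- expand.grid(x = c(0, 20, 40), y = c(0, 20, 40))
  k1 <- knn_distances(g, k = 1)
  expect_true(all(k1$distance == 20))
  k2 <- knn_distances(g, k = 2)
  expect_true(all(k2$distance == 20)) # corners still have 2 neighbors at 20
  k3 <- knn_distances(g, k = 3)
  expect_true(all(k2$distance >= k1$distance))
  expect_true(all(k3$distance >= k2$distance))
  expect_error(knn_distances(two, k = 2), "k \\+ 1")
})

test_that("CSR NND distribution matches the Rayleigh closed form", {
  meta <- acquisition_meta(10, 0.1, field_width = 6000, field_height = 6000)
  rho <- 422e-6 # per nm^2
  sites <- place_sites_csr(422, meta, seed = 21, guard = 120)
  nnd <- knn_distances(sites, k = 1, field = c(6000, 6000), guard = 120)
  # mean -> 1 / (2 sqrt(rho))
  expect_lt(abs(attr(nnd, "mean") - 1 / (2 * sqrt(rho))), 1)
  # CDF -> 1 - exp(-pi rho r^2), Kolmogorov-Smirnov at the 1% level
  ks <- suppressWarnings(stats::ks.test(
    nnd$distance, function(r) 1 - exp(-pi * rho * r^2)
  ))
  expect_gt(ks$p.value, 0.01)
  # fraction below threshold agrees with the analytic CDF
  f40 <- fraction_below(nnd, 40)
  expect_lt(abs(f40 - (1 - exp(-pi * rho * 40^2))), 0.04)
})

test_that("density estimation counts points per area", {
  pts <- data.frame(x = runif(100, 0, 1000), y = runif(100, 0, 1000))
  expect_equal(estimate_density(pts, roi_rect(0, 1000, 0, 1000)), 100)
  expect_equal(estimate_density(pts, roi_rect(2000, 3000, 0, 1000)), 0)
  meta <- acquisition_meta(10, 0.1, field_width = 5000, field_height = 5000)
  sites <- place_sites_csr(422, meta, seed = 2, guard = 0)
  got <- estimate_density(sites, roi_rect(0, 5000, 0, 5000))
  expect_lt(abs(got - 422), 3 * sqrt(422 / 25))
})

test_that("the t-test reproduces a hand-computed fixture and edge cases", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  got <- two_sided_t_test(a, b, variant = "pooled")
  # hand computation: means 3 and 4, pooled variance 2.5,
  # SE = sqrt(2.5 (1/5 + 1/5)) = 1, so t = -1, df = 8
  expect_equal(got$statistic, -1, tolerance = 1e-9)
  expect_equal(got$df, 8)
  expect_equal(got$p_value, 2 * stats::pt(-1, 8), tolerance = 1e-9)
  # identical samples
  expect_equal(two_sided_t_test(a, a)$p_value, 1)
  # degenerate: zero variance
  expect_equal(two_sided_t_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(two_sided_t_test(c(2, 2, 2), c(3, 3))$p_value, 0)
})

test_that("t-test p-values are uniform under the null", {
  withr::with_seed(31, {
    p <- vapply(1:600, function(i) {
      two_sided_t_test(rnorm(100), rnorm(100))$p_value
    }, numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
  })
})

test_that("fraction_below uses a strict threshold", {
  expect_equal(fraction_below(c(50, 50, 50), 40), 0)
  expect_equal(fraction_below(c(10, 39.9, 40, 70), 40), 0.5)
  expect_error(fraction_below(c(1, 2), 0), "threshold")
})

test_that("aggregated force is the density-force product lower bound", {
  got <- aggregated_force(89, 9)
  expect_equal(got$aggregated, 801)
  expect_gte(got$aggregated, 800)
  expect_equal(aggregated_force(0, 9)$aggregated, 0)
  expect_equal(aggregated_force(422, 9)$aggregated, 3798)
})

# a small scenario whose full pipeline runs in well under a second
calib_config <- function() {
  pipeline_config(
    scenario = list(density = 422, field_width = 1000, field_height = 1000),
    acquisition = list(n_frames = 25000, exposure = 0.1),
    kinetics = list(imager_conc = 750e-12),
    spatial = list(n_reps = 1L)
  )
}

calib_experiment <- function(seed, config) {
  meta <- acquisition_meta(config$acquisition$n_frames,
                           config$acquisition$exposure,
                           field_width = config$scenario$field_width,
                           field_height = config$scenario$field_height)
  sites <- place_sites_csr(config$scenario$density, meta, seed = seed,
                           guard = config$spatial$guard)
  locs <- render_localizations(sites,
                               do.call(kinetics_config, config$kinetics),
                               do.call(emission_model, config$emission),
                               seed = seed + 1L)
  detect_sites(locs, radius = config$detect$radius,
               mean_frame_window = config$detect$mean_frame_window,
               meta = meta)
}

test_that("matched null is reproducible and null-vs-null is calibrated", {
  cfg <- calib_config()
  roi <- roi_rect(0, 1000, 0, 1000)
  det <- calib_experiment(77, cfg)
  cmp1 <- csr_matched_null(det, roi, cfg, n_reps = 2, seed = 5,
                           placement_density = 422)
  cmp2 <- csr_matched_null(det, roi, cfg, n_reps = 2, seed = 5,
                           placement_density = 422)
  expect_identical(glance(cmp1), glance(cmp2))
  expect_error(csr_matched_null(det, roi, cfg, n_reps = 0), "n_reps")

  # calibration: experiment is itself a CSR pipeline realization placed at
  # the same known density; rejection at alpha = 0.05 should be ~5%
  pvals <- vapply(1:200, function(s) {
    det_s <- calib_experiment(3000 + 7 * s, cfg)
    cmp <- csr_matched_null(det_s, roi, cfg, n_reps = 1,
                            seed = 60000 + 11 * s,
                            placement_density = 422)
    cmp$p_value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  # binomial 3 SE band around 0.05 with 200 draws
  expect_gte(rej, 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Thomas-clustered input is detected as non-random with power", {
  # the clustered case of interest: open sensors in adhesions at ~89/um^2;
  # 3 x 3 um gives the block t-test enough sites for full power
  cfg <- pipeline_config(
    scenario = list(density = 89, field_width = 3000, field_height = 3000),
    acquisition = list(n_frames = 25000),
    kinetics = list(imager_conc = 750e-12)
  )
  roi <- roi_rect(0, 3000, 0, 3000)
  meta <- acquisition_meta(25000, 0.1, field_width = 3000,
                           field_height = 3000)
  hits <- vapply(1:20, function(s) {
    sites <- place_sites_clustered(89 / 3, 3, 15, meta,
                                   seed = 500 + s, guard = 100)
    locs <- render_localizations(sites, kinetics_config(imager_conc = 750e-12),
                                 emission_model(), seed = 600 + s)
    det <- detect_sites(locs, meta = meta)
    cmp <- csr_matched_null(det, roi, cfg, n_reps = 1, seed = 700 + s)
    (cmp$p_value < 0.05) && (cmp$relative_excess > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("detection inflates the CSR mean NND", {
  cfg <- calib_config()
  det <- calib_experiment(123, cfg)
  nnd_det <- knn_distances(det, k = 1, field = c(1000, 1000), guard = 100)
  raw <- 1 / (2 * sqrt(422e-6))
  expect_gt(attr(nnd_det, "mean"), raw)
})
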