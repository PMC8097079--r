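# Synthetic DNA-PAINT generator: site placement, binding kinetics and
# localization rendering.

small_meta <- function(w = 2000, frames = 1000, exposure = 0.1) {
  acquisition_meta(frames, exposure, field_width = w, field_height = w)
}

test_that("CSR placement is Poisson with the right intensity", {
  meta <- acquisition_meta(10, 0.1, field_width = sqrt(10) * 1000,
                           field_height = sqrt(10) * 1000)
  counts <- vapply(1:200, function(s) {
    nrow(place_sites_csr(422, meta, seed = s, guard = 0))
  }, numeric(1))
  lambda <- 422 * 10
  # mean within 3 standard errors of 422 sites/um^2 x 10 um^2
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # Poisson dispersion
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("fixed-count override and degenerate densities work", {
  meta <- small_meta()
  expect_equal(nrow(place_sites_csr(1, meta, seed = 1, n_sites = 0)), 0)
  expect_equal(nrow(place_sites_csr(1, meta, seed = 1, n_sites = 7)), 7)
  expect_error(place_sites_csr(0, meta), "density")
  expect_error(place_sites_csr(-5, meta), "density")
})

test_that("raw CSR nearest-neighbor distances match 1 / (2 sqrt(rho))", {
  meta <- acquisition_meta(1000, 0.1, field_width = 5000,
                           field_height = 5000)
  sites <- place_sites_csr(422, meta, seed = 11, guard = 100)
  nnd <- knn_distances(sites, k = 1, field = c(5000, 5000), guard = 100)
  want <- 1 / (2 * sqrt(422e-6)) # = 24.34 nm
  expect_lt(abs(attr(nnd, "mean") - want),
            3 * attr(nnd, "sd") / sqrt(attr(nnd, "n")) + 0.35)
})

test_that("CSR maps pass a chi-square uniformity screen", {
  meta <- small_meta()
  pvals <- vapply(1:100, function(s) {
    m <- place_sites_csr(500, meta, seed = s, guard = 0)
    gx <- cut(m$x, seq(0, 2000, length.out = 11))
    gy <- cut(m$y, seq(0, 2000, length.out = 11))
    suppressWarnings(stats::chisq.test(table(gx, gy))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("Thomas placement has the right intensity and degenerate limit", {
  meta <- small_meta()
  counts <- vapply(1:100, function(s) {
    nrow(place_sites_clustered(25, 4, 15, meta, seed = s, guard = 0))
  }, numeric(1))
  lambda <- 25 * 4 * 4 # parents/um^2 x offspring x 4 um^2
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(2 * lambda / 100))
  # spread 0 with fixed offspring two: coincident pairs
  m <- place_sites_clustered(25, 2, 0, meta, seed = 5)
  d <- as.matrix(dist(cbind(m$x, m$y)))
  diag(d) <- Inf
  frac_coincident <- mean(apply(d, 1, min) < 1e-9)
  expect_gt(frac_coincident, 0.3) # Poisson(2) gives pairs often enough
})

test_that("clustered maps show excess short NND relative to CSR", {
  meta <- acquisition_meta(1000, 0.1, field_width = 4000,
                           field_height = 4000)
  th <- place_sites_clustered(89 / 4, 4, 15, meta, seed = 2, guard = 100)
  cs <- place_sites_csr(89, meta, seed = 2, guard = 100)
  f_th <- fraction_below(knn_distances(th, k = 1, field = c(4000, 4000),
                                       guard = 100), 40)
  f_cs <- fraction_below(knn_distances(cs, k = 1, field = c(4000, 4000),
                                       guard = 100), 40)
  expect_gt(f_th, f_cs)
})

test_that("binding events are Poisson in time with exponential durations", {
  meta <- acquisition_meta(250000, 0.1, field_width = 100,
                           field_height = 100)
  kin <- kinetics_config(k_on = 1.6e6, imager_conc = 75e-12,
                         mean_bright = 0.5)
  ev <- simulate_site_events(10000, kin, meta, seed = 3)
  # analytic mean: 1.6e6 x 75e-12 x 25000 s = 3 events per site
  n_per_site <- tabulate(ev$site, nbins = 10000)
  expect_lt(abs(mean(n_per_site) - 3), 3 * sqrt(3 / 10000))
  expect_gt(var(n_per_site) / mean(n_per_site), 0.9)
  expect_lt(var(n_per_site) / mean(n_per_site), 1.1)
  # doubling the concentration doubles the mean
  kin2 <- kinetics_config(imager_conc = 150e-12)
  ev2 <- simulate_site_events(10000, kin2, meta, seed = 4)
  expect_lt(abs(nrow(ev2) / nrow(ev) - 2), 0.1)
  # zero concentration: no events ever
  ev0 <- simulate_site_events(500, kinetics_config(imager_conc = 0), meta,
                              seed = 5)
  expect_equal(nrow(ev0), 0)
  # durations truncated at acquisition end
  expect_true(all(ev$start + ev$duration <= 25000 + 1e-6))
})

test_that("rendering respects precision, frames and bookkeeping", {
  meta <- acquisition_meta(50000, 0.1, field_width = 400,
                           field_height = 400)
  sites <- place_sites_csr(10, meta, seed = 1, n_sites = 5, guard = 0)
  # sigma -> 0: localizations exactly at site positions
  locs0 <- render_localizations(sites, kinetics_config(imager_conc = 1e-9),
                                emission_model(sigma_loc = 0), seed = 2)
  expect_true(all(locs0$x %in% sites$x))
  expect_true(all(locs0$y %in% sites$y))
  # sample sd around an isolated site recovers sigma_loc within 5%
  one <- place_sites_csr(1, meta, seed = 1, n_sites = 1, guard = 0)
  locs <- render_localizations(one, kinetics_config(imager_conc = 30e-9),
                               emission_model(sigma_loc = 4), seed = 3)
  expect_gt(nrow(locs), 1000)
  expect_lt(abs(sd(locs$x) / 4 - 1), 0.05)
  expect_lt(abs(sd(locs$y) / 4 - 1), 0.05)
  expect_true(all(locs$frame >= 0 & locs$frame < 50000))
})

test_that("a one-frame event yields exactly one localization in that frame", {
  meta <- acquisition_meta(100, 0.1, field_width = 100, field_height = 100)
  # construct directly: event fully inside frame 42
  f0 <- floor(4.25 / 0.1)
  expect_equal(f0, 42)
  # kinetics with tiny bright time rarely spans a frame boundary
  sites <- place_sites_csr(1, meta, seed = 1, n_sites = 50, guard = 0)
  locs <- render_localizations(sites,
                               kinetics_config(imager_conc = 2e-9,
                                               mean_bright = 1e-4),
                               emission_model(), seed = 4)
  ev <- simulate_site_events(50, kinetics_config(imager_conc = 2e-9,
                                                 mean_bright = 1e-4),
                             meta, seed = 4)
  # almost every event covers one frame; localization count matches the
  # per-event frame span exactly
  spans <- floor(pmin(ev$start + ev$duration, 10 - 1e-9) / 0.1) -
    floor(ev$start / 0.1) + 1
  expect_equal(nrow(locs), sum(spans))
})

test_that("rendering is deterministic given a seed", {
  meta <- small_meta(frames = 2000)
  sites <- place_sites_csr(100, meta, seed = 9)
  a <- render_localizations(sites, kinetics_config(imager_conc = 1e-9),
                            emission_model(), seed = 10)
  b <- render_localizations(sites, kinetics_config(imager_conc = 1e-9),
                            emission_model(), seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- render_localizations(sites, kinetics_config(imager_conc = 1e-9),
                            emission_model(), seed = 11)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("background sites add unspecific localizations", {
  meta <- small_meta(frames = 5000)
  sites <- place_sites_csr(1, meta, seed = 1, n_sites = 1, guard = 0)
  locs <- render_localizations(
    sites, kinetics_config(imager_conc = 5e-9),
    emission_model(background_site_density = 7), seed = 6
  )
  expect_true(any(locs$site < 0))
  expect_true(any(locs$site > 0))
})
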