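# Quality metrics: aligned-cloud precision, NeNA, qPAINT event counting and
# the dip-based unimodality diagnostic.

aligned_fixture <- function(n_sites = 100, per_site = 100, sigma = 3.9,
                            seed = 1, spacing = 500) {
  withr::with_seed(seed, {
    side <- ceiling(sqrt(n_sites))
    g <- expand.grid(x = seq(200, by = spacing, length.out = side),
                     y = seq(200, by = spacing, length.out = side))
    g <- g[seq_len(n_sites), ]
    meta <- acquisition_meta(1000, 0.1,
                             field_width = max(g$x) + 200,
                             field_height = max(g$y) + 200)
    site <- rep(seq_len(n_sites), each = per_site)
    locs <- loc_table(data.frame(
      x = g$x[site] + rnorm(length(site), 0, sigma),
      y = g$y[site] + rnorm(length(site), 0, sigma),
      frame = rep_len(0:999, length(site))
    ), meta)
    sites <- detect_sites(locs, radius = 12)
    list(locs = locs, sites = sites, truth = g)
  })
}

test_that("center-of-mass alignment is translation-invariant and centered", {
  fix <- aligned_fixture(n_sites = 20, per_site = 50)
  cloud <- com_align_sum(fix$locs, fix$sites)
  expect_lt(abs(mean(cloud$dx)), 1e-9)
  expect_lt(abs(mean(cloud$dy)), 1e-9)
  # translating all raw localizations leaves the cloud unchanged
  moved <- fix$locs
  moved$x <- moved$x + 123
  moved$y <- moved$y - 77
  sites2 <- fix$sites
  sites2$x <- sites2$x + 123
  sites2$y <- sites2$y - 77
  cloud2 <- com_align_sum(moved, sites2)
  expect_equal(cloud$dx, cloud2$dx, tolerance = 1e-9)
  # two identical sites offset by 500 nm superimpose exactly
  m <- acquisition_meta(10, 0.1, field_width = 1000, field_height = 1000)
  base <- data.frame(x = c(0, 3, -3), y = c(0, 4, -4), frame = 0:2)
  two <- rbind(base, transform(base, x = x + 500))
  sites <- tibble::tibble(site = 1:2, x = c(0, 500), y = 0)
  attr(sites, "radius") <- 10
  cl <- com_align_sum(loc_table(two, m), sites)
  expect_equal(cl$dx[1:3], cl$dx[4:6], tolerance = 1e-12)
})

test_that("sites with fewer than two members are skipped with a warning", {
  m <- acquisition_meta(10, 0.1, field_width = 1000, field_height = 1000)
  locs <- loc_table(data.frame(x = c(0, 1, 500), y = 0, frame = 0:2), m)
  sites <- tibble::tibble(site = 1:2, x = c(0, 500), y = 0)
  attr(sites, "radius") <- 10
  expect_warning(cl <- com_align_sum(locs, sites), "skipped")
  expect_equal(attr(cl, "n_sites"), 1)
})

test_that("cross-section precision recovers the simulated sigma", {
  fix <- aligned_fixture(n_sites = 100, per_site = 100, sigma = 3.9)
  cloud <- com_align_sum(fix$locs, fix$sites)
  est <- cross_section_precision(cloud)
  expect_lt(abs(est$sigma - 3.9), 0.15)
  # aligned-cloud sample sd is also ~ sigma per axis
  expect_lt(abs(sd(cloud$dx) - 3.9), 0.15)
  # doubling the bin width moves the estimate by < 2%
  est2 <- cross_section_precision(cloud, bin_width = 2)
  expect_lt(abs(est2$sigma / est$sigma - 1), 0.02)
  # degenerate cloud errors
  degen <- tibble::tibble(dx = rep(0, 100), dy = rep(0, 100))
  expect_error(cross_section_precision(degen), "degenerate")
})

nena_fixture <- function(sigma = 4.1, n_mol = 1500, seed = 2,
                         background = 0) {
  withr::with_seed(seed, {
    field <- 20000
    meta <- acquisition_meta(2000, 0.1, field_width = field,
                             field_height = field)
    mx <- runif(n_mol, 0, field)
    my <- runif(n_mol, 0, field)
    f0 <- sample(0:1998, n_mol, replace = TRUE)
    # each molecule localized in two consecutive frames
    df <- data.frame(
      x = rep(mx, 2) + rnorm(2 * n_mol, 0, sigma),
      y = rep(my, 2) + rnorm(2 * n_mol, 0, sigma),
      frame = c(f0, f0 + 1L)
    )
    if (background > 0) {
      df <- rbind(df, data.frame(x = runif(background, 0, field),
                                 y = runif(background, 0, field),
                                 frame = sample(0:1999, background, TRUE)))
    }
    loc_table(df, meta)
  })
}

test_that("NeNA recovers the localization precision and scales with it", {
  est <- nena_precision(nena_fixture(sigma = 4.1))
  expect_lt(abs(est$sigma - 4.1), 0.2)
  expect_false(est$fit_diagnostics$background_dominated)
  est2 <- nena_precision(nena_fixture(sigma = 8.2, seed = 3))
  expect_lt(abs(est2$sigma / est$sigma - 2), 0.15)
})

test_that("unrelated CSR points give a background-dominated NeNA fit", {
  withr::with_seed(4, {
    field <- 1000
    meta <- acquisition_meta(200, 0.1, field_width = field,
                             field_height = field)
    locs <- loc_table(data.frame(x = runif(6000, 0, field),
                                 y = runif(6000, 0, field),
                                 frame = sample(0:199, 6000, TRUE)), meta)
    est <- nena_precision(locs, r_max = 300)
    expect_true(est$fit_diagnostics$background_dominated)
  })
})

test_that("NeNA and cross-section agree on clean simulated data", {
  fix <- aligned_fixture(n_sites = 100, per_site = 100, sigma = 4.0,
                         seed = 5)
  cs <- cross_section_precision(com_align_sum(fix$locs, fix$sites))
  ne <- nena_precision(nena_fixture(sigma = 4.0, seed = 6))
  expect_lt(abs(cs$sigma - ne$sigma) / ne$sigma, 0.15)
})

test_that("binding events are counted as gap-tolerant frame runs", {
  expect_equal(count_binding_events(c(10, 11, 12, 500, 501), 1), 2L)
  expect_equal(count_binding_events(integer(0)), 0L)
  expect_equal(count_binding_events(c(5)), 1L)
  # a single missed frame is bridged at tol 1, not at tol 0
  expect_equal(count_binding_events(c(10, 12), 1), 1L)
  expect_equal(count_binding_events(c(10, 12), 0), 2L)
  # order invariance and monotone in gap tolerance
  withr::with_seed(7, {
    for (i in 1:20) {
      f <- sample(1:300, 40)
      expect_equal(count_binding_events(f, 2),
                   count_binding_events(sample(f), 2))
      tols <- vapply(0:5, function(g) count_binding_events(f, g), integer(1))
      expect_true(all(diff(tols) <= 0))
    }
  })
})

test_that("event counts scale linearly with imager concentration", {
  meta <- acquisition_meta(20000, 0.1, field_width = 2000,
                           field_height = 2000)
  count_mean <- function(conc, seed) {
    sites <- place_sites_csr(1, meta, seed = 1, n_sites = 200, guard = 0)
    ev <- simulate_site_events(200, kinetics_config(imager_conc = conc),
                               meta, seed = seed)
    nrow(ev) / 200
  }
  m75 <- mean(vapply(1:5, function(s) count_mean(75e-11, s), numeric(1)))
  m150 <- mean(vapply(1:5, function(s) count_mean(150e-11, s), numeric(1)))
  expect_lt(abs(m150 / m75 - 2), 0.15)
})

test_that("dip statistic matches hand-derived exact values", {
  # four points 0, .1, .9, 1: linear program solved by hand gives 2/9
  expect_equal(dip_statistic(c(0, 0.1, 0.9, 1)), 2 / 9, tolerance = 1e-6)
  # equally spaced data are perfectly unimodal-compatible
  expect_equal(dip_statistic(1:10), 0.05, tolerance = 1e-9)
  expect_equal(dip_statistic(seq(0, 1, length.out = 100)), 0.005,
               tolerance = 1e-5)
  # two points: the maximal dip
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  # two tight 3-point clumps: 0.245 by the flattened-clump argument
  expect_equal(dip_statistic(c(0, 0.01, 0.02, 1, 1.01, 1.02)), 0.245,
               tolerance = 1e-6)
  expect_equal(dip_statistic(rep(3, 10)), 0.05)
})

test_that("dip statistic agrees with an independent feasibility oracle", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(4:14, 1)
      x <- switch(sample(3, 1), runif(n), rnorm(n),
                  c(runif(ceiling(n / 2)), 3 + runif(floor(n / 2))))
      expect_equal(dip_statistic(x), dip_oracle(x), tolerance = 1e-4)
    }
  })
})

test_that("dip is scale invariant, bounded, and separates far mixtures", {
  withr::with_seed(18, {
    x <- runif(200)
    expect_equal(dip_statistic(x), dip_statistic(10 * x - 4),
                 tolerance = 1e-7)
    for (i in 1:50) {
      n <- sample(5:200, 1)
      d <- dip_statistic(rnorm(n))
      expect_gte(d, 1 / (2 * n) - 1e-9)
      expect_lte(d, 0.25 + 1e-9)
    }
    expect_gt(dip_statistic(c(rnorm(150), rnorm(150, 8))),
              3 * dip_statistic(rnorm(300)))
  })
})

events_scenario <- function(seed, dockings = 1) {
  withr::with_seed(seed, {
    meta <- acquisition_meta(25000, 0.1, field_width = 1500,
                             field_height = 1500)
    side <- 11
    g <- expand.grid(x = seq(100, by = 120, length.out = side),
                     y = seq(100, by = 120, length.out = side))
    n_sites <- nrow(g)
    # qPAINT: k docking strands bind like one site with k-fold rate
    docks <- if (length(dockings) == 1) rep(dockings, n_sites) else
      sample(dockings, n_sites, replace = TRUE)
    ev <- simulate_site_events(sum(docks),
                               kinetics_config(imager_conc = 1e-9),
                               meta, seed = seed + 1)
    site_of_dock <- rep(seq_len(n_sites), docks)
    ev$site <- site_of_dock[ev$site]
    f0 <- floor(ev$start / 0.1)
    f1 <- floor(pmin(ev$start + ev$duration, 2500 - 1e-9) / 0.1)
    nf <- as.integer(f1 - f0 + 1)
    idx <- rep.int(seq_len(nrow(ev)), nf)
    locs <- loc_table(data.frame(
      x = g$x[ev$site][idx] + rnorm(sum(nf), 0, 4),
      y = g$y[ev$site][idx] + rnorm(sum(nf), 0, 4),
      frame = as.integer(sequence(nf, from = as.integer(f0)))
    ), meta)
    sites <- tibble::tibble(site = seq_len(n_sites), x = g$x, y = g$y)
    attr(sites, "radius") <- 10
    list(locs = locs, sites = sites)
  })
}

test_that("single-docking sites give a unimodal event-count distribution", {
  ok <- vapply(1:12, function(s) {
    sc <- events_scenario(100 + 13 * s, dockings = 1)
    eh <- events_histogram(sc$locs, sc$sites, n_boot = 150, seed = s)
    isTRUE(attr(eh, "unimodal"))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("qPAINT counts scale with docking-strand number", {
  one <- events_scenario(901, dockings = 1)
  three <- events_scenario(902, dockings = 3)
  e1 <- events_histogram(one$locs, one$sites, n_boot = 50, seed = 1)
  e3 <- events_histogram(three$locs, three$sites, n_boot = 50, seed = 1)
  expect_lt(abs(attr(e3, "mean_events") / attr(e1, "mean_events") - 3), 0.5)
  # 50:50 mixture of 1 and 3 dockings pushes the dip up
  mix <- events_scenario(903, dockings = c(1, 3))
  emix <- events_histogram(mix$locs, mix$sites, n_boot = 50, seed = 2)
  expect_gt(attr(emix, "dip"), attr(e1, "dip"))
})

test_that("too few sites for an event histogram errors", {
  sc <- events_scenario(950)
  expect_error(events_histogram(sc$locs, sc$sites[1, ]), "10 sites")
})

test_that("isolated-site selection enforces the separation", {
  sites <- tibble::tibble(site = 1:4, x = c(0, 50, 500, 1000), y = 0)
  sel <- select_isolated(sites, min_separation = 100)
  expect_equal(sel$x, c(500, 1000))
  sel2 <- select_isolated(sites, min_separation = 100, n = 1)
  expect_equal(nrow(sel2), 1)
})
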