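# Synthetic DNA-PAINT acquisitions: ground-truth site maps (CSR or Thomas
# clustered), binding-event kinetics, and localization rendering. This module
# stands in for the microscope: it simulates directly at the localization
# level (binding events -> one localization per overlapped frame, perturbed
# by the localization precision), which preserves the statistical structure
# the downstream cluster detection and NND analysis consume.

#' Binding-kinetics configuration
#'
#' Second-order imager binding: events arrive at each docking site as a
#' Poisson process with rate `k_on * imager_conc`, and bright times are
#' exponential with mean `mean_bright`.
#'
#' @param k_on Imager on-rate in 1/(M s); default 1.6e6, the standard
#'   DNA-PAINT docking/imager value.
#' @param imager_conc Imager concentration in molar (e.g. `75e-12` for
#'   75 pM).
#' @param mean_bright Mean bright (bound) time in seconds (default 0.5).
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(k_on = 1.6e6, imager_conc = 75e-12,
                            mean_bright = 0.5) {
  stopifnot(k_on > 0, imager_conc >= 0, mean_bright > 0)
  structure(list(k_on = k_on, imager_conc = imager_conc,
                 mean_bright = mean_bright),
            class = "kinetics_config")
}

#' Emission model
#'
#' @param sigma_loc Localization precision (per-axis Gaussian sigma) in nm;
#'   default 4.0, matching a NeNA precision of ~4 nm.
#' @param mean_photons Mean photon count recorded per localization
#'   (bookkeeping only; no photon thresholding is applied).
#' @param background_site_density Density of unspecific background docking
#'   sites in 1/um^2 (default 0) that bind imager with the same kinetics.
#' @return A list of class `emission_model`.
#' @export
emission_model <- function(sigma_loc = 4.0, mean_photons = 5000,
                           background_site_density = 0) {
  stopifnot(sigma_loc >= 0, background_site_density >= 0)
  structure(list(sigma_loc = sigma_loc, mean_photons = mean_photons,
                 background_site_density = background_site_density),
            class = "emission_model")
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

.site_map <- function(x, y, label, meta, density, guard) {
  out <- tibble::tibble(site = seq_along(x), x = x, y = y, label = label)
  attr(out, "meta") <- meta
  attr(out, "density") <- density
  attr(out, "guard") <- guard
  class(out) <- c("site_map", class(out))
  out
}

#' Place molecular sites by complete spatial randomness
#'
#' Homogeneous Poisson point process: the number of sites is Poisson with
#' mean `density * area` and positions are i.i.d. uniform. Sites are placed
#' in the field enlarged by a guard band on every side, so that detection
#' and nearest-neighbor statistics restricted to the core field are free of
#' edge bias.
#'
#' @param density Site density in 1/um^2 (> 0 unless `n_sites` is given).
#' @param meta An [acquisition_meta()] with `field_width`/`field_height`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param guard Guard-band width in nm (default 100) added on every side.
#' @param n_sites Fixed site count overriding the Poisson draw (may be 0).
#' @return A `site_map` tibble: columns `site`, `x`, `y` (nm), `label`
#'   (ground-truth cluster id, `NA` for CSR).
#' @examples
#' meta <- acquisition_meta(1000, 0.1, field_width = 2000, field_height = 2000)
#' place_sites_csr(422, meta, seed = 1)
#' @export
place_sites_csr <- function(density, meta, seed = NULL, guard = 100,
                            n_sites = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"),
            !is.null(meta$field_width), !is.null(meta$field_height))
  if (is.null(n_sites) && density <= 0) {
    stop("`density` must be > 0", call. = FALSE)
  }
  w <- meta$field_width + 2 * guard
  h <- meta$field_height + 2 * guard
  .with_seed(seed, {
    n <- n_sites %||% stats::rpois(1, density * 1e-6 * w * h)
    .site_map(
      x = stats::runif(n, -guard, meta$field_width + guard),
      y = stats::runif(n, -guard, meta$field_height + guard),
      label = rep(NA_integer_, n),
      meta = meta, density = density, guard = guard
    )
  })
}

#' Place clustered sites (Thomas process)
#'
#' Poisson-distributed parents with Poisson-distributed offspring displaced
#' by an isotropic Gaussian; the positive control for clustering detection.
#' Total intensity is `parent_density * offspring_per_parent`.
#'
#' @param parent_density Parent density in 1/um^2.
#' @param offspring_per_parent Mean offspring per parent.
#' @param spread_sigma Gaussian displacement sigma in nm.
#' @inheritParams place_sites_csr
#' @return A `site_map` tibble; `label` records the parent id.
#' @export
place_sites_clustered <- function(parent_density, offspring_per_parent,
                                  spread_sigma, meta, seed = NULL,
                                  guard = 100) {
  stopifnot(parent_density > 0, offspring_per_parent > 0, spread_sigma >= 0,
            inherits(meta, "acquisition_meta"))
  w <- meta$field_width + 2 * guard
  h <- meta$field_height + 2 * guard
  .with_seed(seed, {
    n_par <- stats::rpois(1, parent_density * 1e-6 * w * h)
    px <- stats::runif(n_par, -guard, meta$field_width + guard)
    py <- stats::runif(n_par, -guard, meta$field_height + guard)
    n_off <- stats::rpois(n_par, offspring_per_parent)
    parent <- rep.int(seq_len(n_par), n_off)
    n <- length(parent)
    x <- px[parent] + stats::rnorm(n, 0, spread_sigma)
    y <- py[parent] + stats::rnorm(n, 0, spread_sigma)
    keep <- x >= -guard & x <= meta$field_width + guard &
      y >= -guard & y <= meta$field_height + guard
    .site_map(x[keep], y[keep], parent[keep], meta,
              density = parent_density * offspring_per_parent, guard = guard)
  })
}

#' Simulate binding events at docking sites
#'
#' For each site, binding events arrive as a Poisson process with rate
#' `k_on * imager_conc` over the total acquisition time
#' `n_frames * exposure`; event durations are exponential with mean
#' `mean_bright` and are truncated at the end of the acquisition.
#'
#' @param n_sites Number of sites to simulate.
#' @param kinetics A [kinetics_config()].
#' @param meta An [acquisition_meta()].
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with columns `site`, `start` (s), `duration` (s, after
#'   truncation).
#' @export
simulate_site_events <- function(n_sites, kinetics, meta, seed = NULL) {
  stopifnot(inherits(kinetics, "kinetics_config"),
            inherits(meta, "acquisition_meta"))
  t_total <- meta$n_frames * meta$exposure
  rate <- kinetics$k_on * kinetics$imager_conc
  .with_seed(seed, {
    n_events <- stats::rpois(n_sites, rate * t_total)
    site <- rep.int(seq_len(n_sites), n_events)
    n <- length(site)
    start <- stats::runif(n, 0, t_total)
    duration <- pmin(stats::rexp(n, 1 / kinetics$mean_bright),
                     t_total - start)
    tibble::tibble(site = site, start = start, duration = duration)
  })
}

#' Render a localization table from a site map
#'
#' Each binding event contributes one localization per camera frame it
#' overlaps (partial overlap included; no photon thresholding), at the site
#' position perturbed by isotropic Gaussian noise of sigma `sigma_loc` drawn
#' independently per localization. Unspecific background sites, if
#' `background_site_density > 0`, are placed by CSR over the same extended
#' field and imaged with the same kinetics.
#'
#' @param sites A `site_map` from [place_sites_csr()] or
#'   [place_sites_clustered()].
#' @param kinetics A [kinetics_config()].
#' @param emission An [emission_model()].
#' @param seed Integer seed, or `NULL`.
#' @return A `loc_table` with columns `x`, `y`, `frame`, `photons`, `site`
#'   (ground-truth site id; background sites are negative).
#' @examples
#' meta <- acquisition_meta(5000, 0.1, field_width = 500, field_height = 500)
#' sites <- place_sites_csr(100, meta, seed = 1)
#' locs <- render_localizations(sites, kinetics_config(imager_conc = 5e-9),
#'                              emission_model(), seed = 1)
#' @export
render_localizations <- function(sites, kinetics = kinetics_config(),
                                 emission = emission_model(), seed = NULL) {
  stopifnot(inherits(sites, "site_map"), inherits(emission, "emission_model"))
  meta <- attr(sites, "meta", exact = TRUE)
  guard <- attr(sites, "guard", exact = TRUE) %||% 0
  .with_seed(seed, {
    sx <- sites$x
    sy <- sites$y
    ids <- sites$site
    if (emission$background_site_density > 0) {
      bg <- place_sites_csr(emission$background_site_density, meta,
                            seed = NULL, guard = guard)
      sx <- c(sx, bg$x)
      sy <- c(sy, bg$y)
      ids <- c(ids, -bg$site)
    }
    ev <- simulate_site_events(length(sx), kinetics, meta, seed = NULL)
    if (nrow(ev) == 0) {
      out <- tibble::tibble(x = numeric(), y = numeric(), frame = integer(),
                            photons = numeric(), site = integer())
      return(loc_table(out, meta))
    }
    f0 <- floor(ev$start / meta$exposure)
    f1 <- floor(pmin(ev$start + ev$duration,
                     meta$n_frames * meta$exposure - 1e-9) / meta$exposure)
    n_per_event <- as.integer(f1 - f0 + 1)
    loc_event <- rep.int(seq_len(nrow(ev)), n_per_event)
    frame <- as.integer(sequence(n_per_event, from = as.integer(f0)))
    loc_site_row <- ev$site[loc_event]
    n <- length(frame)
    out <- tibble::tibble(
      x = sx[loc_site_row] + stats::rnorm(n, 0, emission$sigma_loc),
      y = sy[loc_site_row] + stats::rnorm(n, 0, emission$sigma_loc),
      frame = frame,
      photons = stats::rpois(n, emission$mean_photons),
      site = ids[loc_site_row]
    )
    out <- out[order(out$frame), ]
    loc_table(out, meta)
  })
}
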