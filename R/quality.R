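# Localization-precision and countability metrics: center-of-mass aligned
# sum clouds with cross-sectional Gaussian fits, NeNA (nearest-neighbor
# based analysis) precision from consecutive-frame localization pairs, and
# qPAINT binding-event counting per site.

#' Select isolated sites
#'
#' Sites with no neighbor within `min_separation`, the programmatic
#' counterpart of picking single sensors by eye; used to build aligned sum
#' clouds from unambiguous single molecules.
#'
#' @param sites A `site_map`.
#' @param min_separation Minimum distance to the nearest other site in nm
#'   (default 100).
#' @param n Optionally cap the number of returned sites (first `n` kept).
#' @return The filtered `site_map`.
#' @export
select_isolated <- function(sites, min_separation = 100, n = NULL) {
  if (nrow(sites) < 2) return(sites)
  d <- .knn_dists(cbind(sites$x, sites$y), cbind(sites$x, sites$y), 2)[, 2]
  out <- sites[d >= min_separation, , drop = FALSE]
  if (!is.null(n) && nrow(out) > n) out <- out[seq_len(n), , drop = FALSE]
  out
}

#' Center-of-mass aligned sum cloud
#'
#' Translates each site's member localizations by minus the site centroid
#' and pools them: the super-resolution analogue of summing aligned single
#' molecule images. Sites with fewer than two members are skipped with a
#' warning.
#'
#' @param table A localization table with `x`, `y`.
#' @param sites A `site_map`; membership is computed within the detection
#'   radius.
#' @param radius Assignment radius in nm; defaults to the sites' radius.
#' @return An `aligned_cloud` tibble with columns `dx`, `dy` (nm offsets
#'   from the per-site center of mass) and `site`; attribute `n_sites`.
#' @export
com_align_sum <- function(table, sites, radius = NULL) {
  sid <- site_members(table, sites, radius)
  keep <- sid != 0L
  if (!any(keep)) stop("no localizations belong to any site", call. = FALSE)
  counts <- table(sid[keep])
  small <- as.integer(names(counts))[counts < 2]
  if (length(small) > 0) {
    warning(length(small), " site(s) with < 2 members skipped")
    keep <- keep & !(sid %in% small)
  }
  g <- factor(sid[keep])
  dx <- table$x[keep] - stats::ave(table$x[keep], g)
  dy <- table$y[keep] - stats::ave(table$y[keep], g)
  out <- tibble::tibble(dx = dx, dy = dy, site = as.integer(as.character(g)))
  attr(out, "n_sites") <- nlevels(g)
  class(out) <- c("aligned_cloud", class(out))
  out
}

.gaussian_fit_sigma <- function(mids, counts, sigma0) {
  fit <- minpack.lm::nlsLM(
    counts ~ a * exp(-(mids - mu)^2 / (2 * sigma^2)),
    start = list(a = max(counts), mu = stats::weighted.mean(mids, counts),
                 sigma = sigma0),
    lower = c(a = 0, mu = -Inf, sigma = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  list(sigma = abs(stats::coef(fit)[["sigma"]]),
       resid_norm = sqrt(sum(stats::resid(fit)^2)) / sum(counts))
}

#' Localization precision from an aligned cross-section
#'
#' Histograms the x-offsets of aligned-cloud localizations inside a central
#' band `|dy| <= band_width / 2` and fits a Gaussian by least squares; the
#' fitted sigma is the overall localization precision. The band width is
#' chosen adaptively (two passes: 2 x the sample sigma of the y-offsets)
#' when not supplied.
#'
#' @param cloud An `aligned_cloud` from [com_align_sum()].
#' @param band_width Cross-section band (nm) on the y-offsets, or `NULL`
#'   for the adaptive default.
#' @param bin_width Histogram bin width in nm (default 1).
#' @return A `precision_estimate`: list with `method = "cross_section"`,
#'   `sigma` (nm) and `fit_diagnostics`.
#' @export
cross_section_precision <- function(cloud, band_width = NULL, bin_width = 1) {
  stopifnot(nrow(cloud) > 0, bin_width > 0)
  if (stats::sd(cloud$dx) == 0) {
    stop("degenerate cloud: zero spread in x", call. = FALSE)
  }
  band_width <- band_width %||% (2 * stats::sd(cloud$dy))
  sel <- abs(cloud$dy) <= band_width / 2
  xs <- cloud$dx[sel]
  if (length(xs) < 10) stop("too few localizations in band", call. = FALSE)
  breaks <- seq(floor(min(xs)) - bin_width, ceiling(max(xs)) + bin_width,
                by = bin_width)
  h <- graphics::hist(xs, breaks = breaks, plot = FALSE)
  fit <- .gaussian_fit_sigma(h$mids, h$counts, sigma0 = stats::sd(xs))
  structure(
    list(method = "cross_section", sigma = fit$sigma,
         fit_diagnostics = list(resid_norm = fit$resid_norm,
                                band_width = band_width,
                                n = length(xs))),
    class = "precision_estimate"
  )
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> %s: sigma = %.2f nm\n", x$method, x$sigma))
  invisible(x)
}

#' @export
glance.precision_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, sigma = x$sigma,
                 resid_norm = x$fit_diagnostics$resid_norm,
                 n = x$fit_diagnostics$n %||% NA_integer_)
}

#' NeNA localization precision
#'
#' Nearest-neighbor based analysis: repeated localizations of the same
#' molecule in consecutive frames are displaced by the localization error
#' twice, so their nearest-neighbor distance density follows
#' `p(d) = d / (2 sigma^2) exp(-d^2 / (4 sigma^2))`. The distances between
#' each localization and its nearest neighbor in the following frame are
#' collected and that density -- plus a linear background term for
#' unrelated near-by molecules -- is fitted to the binned distances.
#'
#' @param table A `loc_table` with >= 1000 rows spanning >= 2 frames.
#' @param r_max Maximum pair distance considered, nm (default 100).
#' @param bin_width Histogram bin width in nm (default 1).
#' @param background Include the linear background component
#'   (default `TRUE`).
#' @return A `precision_estimate` with `method = "nena"`, `sigma` (nm) and
#'   `fit_diagnostics` (residual norm, background weight, flag
#'   `background_dominated`).
#' @export
nena_precision <- function(table, r_max = 100, bin_width = 1,
                           background = TRUE) {
  if (nrow(table) < 1000) {
    stop("NeNA needs at least 1000 localizations", call. = FALSE)
  }
  by_frame <- split(seq_len(nrow(table)), table$frame)
  frames <- as.integer(names(by_frame))
  if (length(frames) < 2) stop("NeNA needs >= 2 distinct frames", call. = FALSE)
  d <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    j <- match(frames[i] + 1L, frames)
    if (is.na(j)) next
    a <- by_frame[[i]]
    b <- by_frame[[j]]
    nn <- RANN::nn2(cbind(table$x[b], table$y[b]),
                    cbind(table$x[a], table$y[a]), k = 1)
    d[[i]] <- nn$nn.dists[, 1]
  }
  d <- unlist(d, use.names = FALSE)
  d <- d[d <= r_max]
  if (length(d) < 100) {
    stop("too few consecutive-frame neighbor pairs for NeNA", call. = FALSE)
  }
  breaks <- seq(0, r_max, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  n_tot <- length(d)
  mids <- h$mids
  counts <- h$counts
  sigma0 <- stats::quantile(d, 0.25) / sqrt(2)
  if (background) {
    # components are densities on [0, r_max]; w is the same-molecule weight
    fit <- minpack.lm::nlsLM(
      counts ~ n_tot * bin_width *
        (w * mids / (2 * sigma^2) * exp(-mids^2 / (4 * sigma^2)) +
           (1 - w) * 2 * mids / r_max^2),
      start = list(sigma = as.numeric(sigma0), w = 0.8),
      lower = c(sigma = 1e-3, w = 0), upper = c(sigma = r_max, w = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    w <- stats::coef(fit)[["w"]]
  } else {
    fit <- minpack.lm::nlsLM(
      counts ~ n_tot * bin_width *
        mids / (2 * sigma^2) * exp(-mids^2 / (4 * sigma^2)),
      start = list(sigma = as.numeric(sigma0)),
      lower = c(sigma = 1e-3), upper = c(sigma = r_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    w <- 1
  }
  # unrelated CSR neighbors also produce a Rayleigh-shaped distance
  # density, with scale sigma_csr = 1 / (2 sqrt(pi rho_frame)); a fitted
  # sigma approaching that scale means the fit tracks unrelated molecules,
  # not repeated localizations
  meta <- attr(table, "meta", exact = TRUE)
  area <- if (!is.null(meta) && !is.null(meta$field_width)) {
    meta$field_width * meta$field_height
  } else {
    diff(range(table$x)) * diff(range(table$y))
  }
  rho_frame <- nrow(table) / length(by_frame) / area
  sigma_csr <- 1 / (2 * sqrt(pi * rho_frame))
  sigma_hat <- stats::coef(fit)[["sigma"]]
  structure(
    list(method = "nena", sigma = sigma_hat,
         fit_diagnostics = list(
           resid_norm = sqrt(sum(stats::resid(fit)^2)) / n_tot,
           same_molecule_weight = w,
           background_dominated = w < 0.5 || sigma_hat > 0.5 * sigma_csr,
           sigma_csr = sigma_csr,
           n_pairs = n_tot
         )),
    class = "precision_estimate"
  )
}

#' Count qPAINT binding events from member frames
#'
#' Runs of member frames separated by at most `gap_tolerance` missing
#' frames belong to one binding event; the count of maximal runs is the
#' event count. Order-invariant.
#'
#' @param frames Integer vector of member frame indices (any order).
#' @param gap_tolerance Maximum number of missing frames bridged within one
#'   event (default 1).
#' @return Integer event count (0 for an empty vector).
#' @examples
#' count_binding_events(c(10, 11, 12, 500, 501)) # 2
#' @export
count_binding_events <- function(frames, gap_tolerance = 1) {
  stopifnot(gap_tolerance >= 0)
  if (length(frames) == 0) return(0L)
  f <- sort(unique(as.integer(frames)))
  if (length(f) == 1) return(1L)
  sum(diff(f) > gap_tolerance + 1L) + 1L
}

#' Per-site binding-event histogram and unimodality diagnostic
#'
#' Counts binding events per detected site and summarizes their
#' distribution: a unimodal distribution supports single molecules per
#' site, a multimodal one indicates sites carrying several docking strands
#' (qPAINT logic: event counts scale with docking-strand number). The
#' Hartigan dip statistic with a bootstrap p-value (uniform null) is the
#' unimodality diagnostic; it is reported, not used as a hard gate.
#'
#' @param table A localization table with `x`, `y`, `frame`.
#' @param sites A `site_map` with >= 10 sites.
#' @param gap_tolerance Frame gap bridged within one event (default 1).
#' @param n_boot Bootstrap replicates for the dip p-value (default 500).
#' @param seed Seed for the bootstrap.
#' @return An `event_counts` object: tibble (`site`, `n_events`) with
#'   attributes `dip`, `p_value`, `unimodal`, `mean_events`.
#' @export
events_histogram <- function(table, sites, gap_tolerance = 1, n_boot = 500,
                             seed = NULL) {
  if (nrow(sites) < 10) {
    stop("need at least 10 sites for an event-count distribution",
         call. = FALSE)
  }
  sid <- site_members(table, sites)
  keep <- sid != 0L
  counts <- vapply(
    split(table$frame[keep], sid[keep]),
    count_binding_events, integer(1), gap_tolerance = gap_tolerance
  )
  out <- tibble::tibble(site = as.integer(names(counts)),
                        n_events = as.integer(counts))
  res <- .with_seed(seed, {
    dip <- dip_statistic(out$n_events + stats::runif(nrow(out), -0.5, 0.5))
    boot <- vapply(seq_len(n_boot), function(i) {
      dip_statistic(stats::runif(nrow(out)))
    }, numeric(1))
    list(dip = dip, boot = boot)
  })
  dip <- res$dip
  boot <- res$boot
  p <- (sum(boot >= dip) + 1) / (n_boot + 1)
  attr(out, "dip") <- dip
  attr(out, "p_value") <- p
  attr(out, "unimodal") <- p > 0.05
  attr(out, "mean_events") <- mean(out$n_events)
  class(out) <- c("event_counts", class(out))
  out
}

#' @export
glance.event_counts <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    mean_events = attr(x, "mean_events", exact = TRUE),
    dip = attr(x, "dip", exact = TRUE),
    dip_p_value = attr(x, "p_value", exact = TRUE),
    unimodal = attr(x, "unimodal", exact = TRUE)
  )
}
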