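# End-to-end orchestration: a validated configuration object, deterministic
# per-stage seeding derived from one global seed, and the
# simulate -> detect -> NND -> CSR-test -> force pipeline with a JSON-able
# summary.

.config_defaults <- function() {
  list(
    seed = 1L,
    scenario = list(density = 422, field_width = 5000, field_height = 5000,
                    clustered = FALSE, parent_density = NULL,
                    offspring_per_parent = NULL, spread_sigma = NULL),
    acquisition = list(n_frames = 250000L, exposure = 0.1, pixel_size = 130),
    kinetics = list(k_on = 1.6e6, imager_conc = 75e-12, mean_bright = 0.5),
    emission = list(sigma_loc = 4.0, mean_photons = 5000,
                    background_site_density = 0),
    detect = list(radius = 10, mean_frame_window = c(0.2, 0.8)),
    spatial = list(k = c(1L, 2L), threshold = 40, guard = 100,
                   n_reps = 0L, threshold_force = 9),
    output_dir = NULL
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()], filling defaults
#' for anything not supplied. Parameters are grouped by stage:
#' `scenario` (site placement), `acquisition`, `kinetics`, `emission`,
#' `detect`, `spatial`, plus a global `seed` and optional `output_dir`.
#' Unknown keys (at either level) are rejected.
#'
#' @param ... Named stage lists or the scalar fields `seed` / `output_dir`,
#'   e.g. `scenario = list(density = 422)`.
#' @return A list of class `pipeline_config` with all defaults filled.
#' @examples
#' pipeline_config(scenario = list(density = 100), seed = 7)
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0("`", unknown, "`", collapse = ", "), call. = FALSE)
  }
  cfg <- defaults
  for (key in names(user)) {
    if (is.list(defaults[[key]])) {
      sub_unknown <- setdiff(names(user[[key]]), names(defaults[[key]]))
      if (length(sub_unknown) > 0) {
        stop("unknown configuration key(s) in `", key, "`: ",
             paste0("`", sub_unknown, "`", collapse = ", "), call. = FALSE)
      }
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  .validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

.validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      scenario$density > 0 || isTRUE(scenario$clustered),
      scenario$field_width > 0, scenario$field_height > 0,
      acquisition$n_frames >= 1, acquisition$exposure > 0,
      kinetics$k_on > 0, kinetics$imager_conc >= 0, kinetics$mean_bright > 0,
      emission$sigma_loc >= 0,
      detect$radius > 0,
      length(detect$mean_frame_window) == 2,
      spatial$threshold > 0, spatial$guard >= 0, spatial$n_reps >= 0
    )
  })
  invisible(cfg)
}

#' Load and save pipeline configurations
#'
#' Reads a YAML or JSON configuration document, validates it against the
#' schema and fills defaults; unknown keys are rejected with the offending
#' key named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` document.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(doc)
}

#' @rdname load_config
#' @param config A `pipeline_config`.
#' @export
save_config <- function(config, path) {
  doc <- unclass(config)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  doc <- lapply(doc, function(x) {
    if (is.list(x)) x[!vapply(x, is.null, logical(1))] else x
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

# one global seed -> reproducible per-stage seeds
.stage_seeds <- function(seed) {
  withr::with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 4L)
    stats::setNames(as.list(s), c("place", "render", "null", "extra"))
  })
}

#' Run the full analysis pipeline
#'
#' Simulates an acquisition (CSR or Thomas-clustered sites, DNA-PAINT
#' kinetics, localization rendering), detects sites, computes density and
#' k-th NND statistics, optionally runs the matched CSR null comparison,
#' and converts density into the aggregated minimal force. Deterministic
#' given the config's `seed` (one global seed spawns fixed per-stage
#' seeds). When `output_dir` is set, localizations, sites and the JSON
#' summary are written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `config`, `sites`
#'   (detected `site_map`), `locs`, `density`, `nnd` (list of
#'   `nnd_result` by k), `csr` (a `csr_comparison` or `NULL`), `force`, and
#'   `summary` (flat named list, the content of the JSON summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- .stage_seeds(config$seed)
  sc <- config$scenario
  meta <- acquisition_meta(
    n_frames = config$acquisition$n_frames,
    exposure = config$acquisition$exposure,
    pixel_size = config$acquisition$pixel_size,
    field_width = sc$field_width, field_height = sc$field_height
  )
  guard <- config$spatial$guard
  sites_true <- if (isTRUE(sc$clustered)) {
    place_sites_clustered(sc$parent_density, sc$offspring_per_parent,
                          sc$spread_sigma, meta, seed = seeds$place,
                          guard = guard)
  } else {
    place_sites_csr(sc$density, meta, seed = seeds$place, guard = guard)
  }
  locs <- render_localizations(
    sites_true, do.call(kinetics_config, config$kinetics),
    do.call(emission_model, config$emission), seed = seeds$render
  )
  detected <- detect_sites(locs, radius = config$detect$radius,
                           mean_frame_window = config$detect$mean_frame_window,
                           meta = meta)
  roi <- roi_rect(0, sc$field_width, 0, sc$field_height)
  density <- estimate_density(detected, roi)
  nnd <- lapply(config$spatial$k, function(k) {
    knn_distances(detected, k = k,
                  field = c(sc$field_width, sc$field_height), guard = guard)
  })
  names(nnd) <- paste0("k", config$spatial$k)
  csr <- NULL
  if (config$spatial$n_reps > 0) {
    csr <- csr_matched_null(
      filter_by_roi(detected, roi), roi, config,
      n_reps = config$spatial$n_reps, seed = seeds$null,
      k = config$spatial$k[1], threshold = config$spatial$threshold
    )
  }
  force <- aggregated_force(density, config$spatial$threshold_force)
  summary <- c(
    list(seed = config$seed, density_per_um2 = density,
         n_sites_detected = nrow(detected)),
    stats::setNames(
      lapply(nnd, function(r) {
        list(mean = attr(r, "mean"), sd = attr(r, "sd"), n = attr(r, "n"))
      }),
      paste0("nnd_", names(nnd))
    ),
    list(aggregated_force_pN_per_um2 = force$aggregated)
  )
  if (!is.null(csr)) {
    summary$csr <- list(
      p_value = csr$p_value,
      mean_null = attr(csr$null, "mean"),
      sd_null = attr(csr$null, "sd"),
      relative_excess = csr$relative_excess
    )
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_localizations(locs, file.path(config$output_dir, "locs.csv"))
    utils::write.csv(tibble::as_tibble(detected),
                     file.path(config$output_dir, "sites.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$output_dir,
                                            "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(config = config, sites = detected, locs = locs, density = density,
         nnd = nnd, csr = csr, force = force, summary = summary),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d sites detected, density %.1f /um^2\n",
    nrow(x$sites), x$density
  ))
  for (nm in names(x$nnd)) {
    cat(sprintf("  NND %s: mean %.1f nm (sd %.1f)\n", nm,
                attr(x$nnd[[nm]], "mean"), attr(x$nnd[[nm]], "sd")))
  }
  if (!is.null(x$csr)) {
    cat(sprintf("  CSR null: p = %.3g, excess %+.0f%%\n",
                x$csr$p_value, 100 * x$csr$relative_excess))
  }
  cat(sprintf("  aggregated force >= %.0f pN/um^2\n", x$force$aggregated))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    density = x$density,
    n_sites = nrow(x$sites),
    nnd1_mean = attr(x$nnd[[1]], "mean", exact = TRUE),
    nnd1_sd = attr(x$nnd[[1]], "sd", exact = TRUE),
    aggregated_force = x$force$aggregated,
    csr_p = if (is.null(x$csr)) NA_real_ else x$csr$p_value
  )
}
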