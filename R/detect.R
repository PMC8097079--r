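# Single-site detection from localization clouds, a neighbor-count variant
# of Ripley's K restricted to one radius: count neighbors within the radius
# for every localization, gradient-ascend the count field to the densest
# localization of each cloud, assign membership within the radius, and keep
# sites whose visits are spread over the acquisition (mean-frame filter).

#' Per-localization neighbor counts
#'
#' The number of other localizations within `radius` of each localization
#' (2D Euclidean distance in x/y; the localization itself is not counted).
#'
#' @param table A data frame with `x` and `y` in nm.
#' @param radius Neighborhood radius in nm (default 10).
#' @return Integer vector of counts, one per row of `table`.
#' @export
neighbor_counts <- function(table, radius = 10) {
  stopifnot(radius > 0)
  if (nrow(table) == 0) return(integer(0))
  .radius_counts(cbind(table$x, table$y), radius)
}

#' Gradient ascent to cluster centers
#'
#' From every localization, repeatedly hop to the within-radius neighbor
#' with the highest neighbor count; among equal counts the lowest-index
#' neighbor is preferred, and a hop is taken only when the neighbor's
#' (count, -index) pair lexicographically exceeds the current one, so the
#' ascent always terminates. Every localization drains to a terminal
#' localization -- the candidate center of its cloud.
#'
#' @param table A data frame with `x`, `y` in nm (rows in canonical order;
#'   [detect_sites()] pre-sorts by x, y, frame).
#' @param counts Neighbor counts from [neighbor_counts()] with the same
#'   radius.
#' @param radius Neighborhood radius in nm.
#' @return Integer vector: for each localization, the row index of its
#'   terminal localization. `sort(unique(.))` is the candidate center set.
#' @export
ascend_to_centers <- function(table, counts, radius = 10) {
  n <- nrow(table)
  stopifnot(length(counts) == n)
  if (n == 0) return(integer(0))
  nxt <- .best_neighbor(cbind(table$x, table$y), counts, radius)
  root <- seq_len(n)
  repeat { # pointer jumping; depth halves every round
    nxt_root <- ifelse(nxt[root] == 0L, root, nxt[root])
    if (identical(nxt_root, root)) break
    root <- nxt_root
  }
  root
}

#' Assign localizations to detected site centers
#'
#' Every localization within `radius` of a center becomes a member of that
#' site; a localization in range of several centers goes to the nearest one
#' (exact ties to the lower center index). Site centers are recomputed as
#' member centroids.
#'
#' @param table A data frame with `x`, `y`, `frame`.
#' @param centers A two-column matrix or data frame of center coordinates.
#' @param radius Assignment radius in nm.
#' @return A list with `sites` (tibble: `site`, `x`, `y`, `members`) and
#'   `assignment` (integer vector per localization, 0 = unassigned).
#' @export
assign_members <- function(table, centers, radius = 10) {
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  if (nrow(centers) == 0 || nrow(table) == 0) {
    return(list(
      sites = tibble::tibble(site = integer(), x = numeric(),
                             y = numeric(), members = integer()),
      assignment = integer(nrow(table))
    ))
  }
  sid <- .nearest_center(centers, cbind(table$x, table$y), radius)
  keep <- sid != 0L
  f <- factor(sid[keep], levels = seq_len(nrow(centers)))
  cx <- tapply(table$x[keep], f, mean)
  cy <- tapply(table$y[keep], f, mean)
  members <- as.integer(table(f))
  occupied <- members > 0L
  sites <- tibble::tibble(
    site = seq_len(sum(occupied)),
    x = as.numeric(cx[occupied]),
    y = as.numeric(cy[occupied]),
    members = members[occupied]
  )
  # relabel assignment to the compacted site ids
  relabel <- integer(nrow(centers))
  relabel[which(occupied)] <- seq_len(sum(occupied))
  assignment <- integer(nrow(table))
  assignment[keep] <- relabel[sid[keep]]
  list(sites = sites, assignment = assignment)
}

#' Mean-frame filter for repetitive binders
#'
#' Keeps sites whose members' mean frame index, as a fraction of the
#' acquisition length, lies within the window (inclusive bounds). Sites
#' visited only early or late in the acquisition are not repetitive binders
#' and are removed.
#'
#' @param sites A site tibble with a `mean_frame_fraction` column.
#' @param window Length-2 fraction pair, default `c(0.2, 0.8)`.
#' @return The filtered site tibble.
#' @export
mean_frame_filter <- function(sites, window = c(0.2, 0.8)) {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  keep <- sites$mean_frame_fraction >= window[1] &
    sites$mean_frame_fraction <= window[2]
  sites[keep, , drop = FALSE]
}

#' Detect single molecular sites from a localization table
#'
#' The full detection pipeline: neighbor counts within `radius`, gradient
#' ascent to candidate centers, single-linkage merging of duplicate
#' terminals closer than `radius / 2`, membership assignment with centroid
#' recomputation (iterated with merging to a fixed point), and the
#' mean-frame filter. The table is canonically pre-sorted by (x, y, frame)
#' so the result does not depend on row order.
#'
#' @param table A `loc_table` (or data frame with `x`, `y`, `frame` and an
#'   `acquisition_meta` in `meta`).
#' @param radius Neighborhood radius in nm (default 10).
#' @param mean_frame_window Inclusive mean-frame fraction window
#'   (default `c(0.2, 0.8)`).
#' @param min_members Minimum localizations per site (default 2): a site
#'   seen once cannot demonstrate repetitive binding, and stray isolated
#'   localizations would otherwise each found a spurious one-member site.
#' @param meta Acquisition metadata; defaults to the table's.
#' @return A `site_map` tibble of detected sites: `site`, `x`, `y` (centroid
#'   nm), `members`, `mean_frame_fraction`; the localization-to-site
#'   assignment is attached as attribute `assignment` (0 = unassigned or
#'   member of a filtered site), aligned with the canonically sorted table
#'   returned in attribute `sorted_order` (row order of the input).
#' @examples
#' meta <- acquisition_meta(1000, 0.1, field_width = 500, field_height = 500)
#' sites <- place_sites_csr(50, meta, seed = 1)
#' locs <- render_localizations(sites, kinetics_config(imager_conc = 2e-9),
#'                              emission_model(), seed = 2)
#' detect_sites(locs)
#' @export
detect_sites <- function(table, radius = 10, mean_frame_window = c(0.2, 0.8),
                         min_members = 2, meta = NULL) {
  meta <- meta %||% attr(table, "meta", exact = TRUE)
  if (is.null(meta)) stop("acquisition metadata required", call. = FALSE)
  guard <- attr(table, "guard", exact = TRUE)
  if (nrow(table) == 0) {
    out <- tibble::tibble(site = integer(), x = numeric(), y = numeric(),
                          members = integer(),
                          mean_frame_fraction = numeric())
    attr(out, "meta") <- meta
    attr(out, "radius") <- radius
    class(out) <- c("site_map", class(out))
    return(out)
  }
  ord <- order(table$x, table$y, table$frame)
  tbl <- as.data.frame(table)[ord, c("x", "y", "frame")]
  counts <- neighbor_counts(tbl, radius)
  roots <- ascend_to_centers(tbl, counts, radius)
  term <- sort(unique(roots))
  centers <- cbind(tbl$x[term], tbl$y[term])
  # duplicate terminals of one cloud: merge within radius/2 (single linkage)
  comp <- .link_components(centers, radius / 2)
  centers <- cbind(
    as.numeric(tapply(centers[, 1], comp, mean)),
    as.numeric(tapply(centers[, 2], comp, mean))
  )
  # assignment and centroid recomputation can bring centers closer than
  # radius/2 again; iterate assign -> centroid -> merge until the
  # assignment stabilizes
  prev_assign <- NULL
  asg <- NULL
  for (pass in 1:20) {
    asg <- assign_members(tbl, centers, radius)
    if (identical(asg$assignment, prev_assign)) break
    prev_assign <- asg$assignment
    centers <- cbind(asg$sites$x, asg$sites$y)
    if (nrow(centers) > 1) {
      comp <- .link_components(centers, radius / 2)
      if (max(comp) < nrow(centers)) {
        centers <- cbind(
          as.numeric(tapply(centers[, 1], comp, mean)),
          as.numeric(tapply(centers[, 2], comp, mean))
        )
        prev_assign <- NULL # membership labels changed meaning
      }
    }
  }
  sites <- asg$sites
  if (min_members > 1) {
    small <- sites$site[sites$members < min_members]
    if (length(small) > 0) {
      asg$assignment[asg$assignment %in% small] <- 0L
      keep_sites <- sites$members >= min_members
      relabel <- integer(nrow(sites))
      relabel[which(keep_sites)] <- seq_len(sum(keep_sites))
      asg$assignment[asg$assignment != 0L] <-
        relabel[asg$assignment[asg$assignment != 0L]]
      sites <- sites[keep_sites, , drop = FALSE]
      sites$site <- seq_len(nrow(sites))
    }
  }
  mf <- tapply(tbl$frame[asg$assignment != 0L],
               factor(asg$assignment[asg$assignment != 0L],
                      levels = sites$site),
               mean)
  sites$mean_frame_fraction <- as.numeric(mf) / meta$n_frames
  kept <- mean_frame_filter(sites, mean_frame_window)
  assignment <- asg$assignment
  assignment[!(assignment %in% kept$site)] <- 0L
  assignment <- match(assignment, kept$site, nomatch = 0L)
  kept$site <- seq_len(nrow(kept))
  attr(kept, "meta") <- meta
  attr(kept, "radius") <- radius
  attr(kept, "guard") <- guard
  attr(kept, "assignment") <- assignment
  attr(kept, "sorted_order") <- ord
  class(kept) <- c("site_map", class(kept))
  kept
}

#' Site membership of localizations
#'
#' Assigns each localization of `table` to the nearest detected site within
#' the detection radius (the assignment [detect_sites()] used internally,
#' recomputed for an arbitrary table).
#'
#' @param table A data frame with `x`, `y`.
#' @param sites A `site_map` from [detect_sites()].
#' @param radius Assignment radius; defaults to the sites' detection radius.
#' @return Integer vector of site ids per localization (0 = none).
#' @export
site_members <- function(table, sites, radius = NULL) {
  radius <- radius %||% attr(sites, "radius", exact = TRUE) %||% 10
  if (nrow(sites) == 0 || nrow(table) == 0) return(integer(nrow(table)))
  .nearest_center(cbind(sites$x, sites$y), cbind(table$x, table$y), radius)
}
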