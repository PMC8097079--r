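# Two-channel axial colocalization: rotate a picked region so the filament
# channel lies along +x, slide a window along x, and compare the mean axial
# (z) positions of the two channels window by window.

#' Rotate a region so the filament channel lies along the x-axis
#'
#' Rigid 2D rotation of all localizations about the reference channel's
#' centroid by minus the orientation of that channel's principal variance
#' axis; z is untouched. Fails when the reference cloud is too isotropic to
#' define an orientation.
#'
#' @param table A localization table with `x`, `y`, optional `z`, and a
#'   `channel` column.
#' @param reference Channel label of the filament (orientation-defining)
#'   channel.
#' @param angle Optional manual rotation angle in radians
#'   (counter-clockwise; overrides the principal-axis estimate).
#' @param min_axis_ratio Minimum sd ratio of the principal axes required to
#'   call the orientation (default 1.2).
#' @return A list with `table` (rotated), `angle` (radians applied,
#'   counter-clockwise) and `center` (rotation center).
#' @export
rotate_to_principal_axis <- function(table, reference, angle = NULL,
                                     min_axis_ratio = 1.2) {
  stopifnot("channel" %in% names(table))
  ref <- table[table$channel == reference, ]
  if (nrow(ref) < 10) {
    stop("need >= 10 localizations in the reference channel", call. = FALSE)
  }
  ctr <- c(mean(ref$x), mean(ref$y))
  if (is.null(angle)) {
    pc <- stats::prcomp(cbind(ref$x, ref$y))
    ratio <- pc$sdev[1] / pc$sdev[2]
    if (!is.finite(ratio) || ratio < min_axis_ratio) {
      stop("reference cloud is nearly isotropic; orientation is ambiguous ",
           "(axis ratio ", signif(ratio, 3), " < ", min_axis_ratio, ")",
           call. = FALSE)
    }
    angle <- -atan2(pc$rotation[2, 1], pc$rotation[1, 1])
    angle <- unname(angle)
    # canonical range (-pi/2, pi/2]: a filament has no direction
    if (angle > pi / 2) angle <- angle - pi
    if (angle <= -pi / 2) angle <- angle + pi
  }
  ca <- cos(angle)
  sa <- sin(angle)
  dx <- table$x - ctr[1]
  dy <- table$y - ctr[2]
  out <- table
  out$x <- ctr[1] + ca * dx - sa * dy
  out$y <- ctr[2] + sa * dx + ca * dy
  list(table = out, angle = angle, center = ctr)
}

#' Sliding-window axial profile of two channels
#'
#' Means of x and z per channel in windows of width `window` slid along the
#' x-axis in steps of `step`; windows in which a channel has fewer than
#' `min_locs` localizations yield `NA` for that channel. `delta_z` is the
#' axial separation channel B minus channel A wherever both are defined
#' (positive = B above A).
#'
#' @param table A rotated localization table with `x`, `z`, `channel`.
#' @param channels Length-2 vector `c(A, B)` of channel labels; `delta_z`
#'   is B - A.
#' @param window Window width in nm (default 75).
#' @param step Step between window centers in nm; default `window`
#'   (non-overlapping tiling). Use e.g. 15 for an overlapping slide.
#' @param min_locs Minimum localizations per channel per window (default 5).
#' @return An `axial_profile` tibble: `window_center`, `mean_x_a`,
#'   `mean_z_a`, `n_a`, `mean_x_b`, `mean_z_b`, `n_b`, `delta_z`.
#' @export
sliding_window_profile <- function(table, channels, window = 75,
                                   step = window, min_locs = 5) {
  stopifnot(window > 0, step > 0, length(channels) == 2,
            all(c("x", "z", "channel") %in% names(table)))
  tab <- table[table$channel %in% channels, ]
  if (nrow(tab) == 0) stop("no localizations in the given channels",
                           call. = FALSE)
  lo <- min(tab$x)
  hi <- max(tab$x)
  centers <- seq(lo + window / 2, max(lo + window / 2, hi - window / 2),
                 by = step)
  win_stats <- function(ch) {
    sub <- tab[tab$channel == ch, ]
    t(vapply(centers, function(ct) {
      inwin <- sub$x >= ct - window / 2 & sub$x < ct + window / 2
      n <- sum(inwin)
      if (n >= min_locs) {
        c(mean(sub$x[inwin]), mean(sub$z[inwin]), n)
      } else {
        c(NA_real_, NA_real_, n)
      }
    }, numeric(3)))
  }
  a <- win_stats(channels[1])
  b <- win_stats(channels[2])
  out <- tibble::tibble(
    window_center = centers,
    mean_x_a = a[, 1], mean_z_a = a[, 2], n_a = as.integer(a[, 3]),
    mean_x_b = b[, 1], mean_z_b = b[, 2], n_b = as.integer(b[, 3]),
    delta_z = b[, 2] - a[, 2]
  )
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "channels") <- channels
  class(out) <- c("axial_profile", class(out))
  out
}

#' Axial separation summary of a profile
#'
#' Summary statistics of `delta_z` over the windows where both channels are
#' populated.
#'
#' @param profile An `axial_profile`.
#' @return A tibble with `n_windows`, `median_delta_z`, `min_delta_z`,
#'   `max_delta_z`, `range_delta_z` (nm); zero rows (with a warning) when
#'   no window is shared.
#' @export
z_separation_summary <- function(profile) {
  dz <- profile$delta_z[!is.na(profile$delta_z)]
  if (length(dz) == 0) {
    warning("no window is populated in both channels")
    return(tibble::tibble(n_windows = integer(), median_delta_z = numeric(),
                          min_delta_z = numeric(), max_delta_z = numeric(),
                          range_delta_z = numeric()))
  }
  tibble::tibble(
    n_windows = length(dz),
    median_delta_z = stats::median(dz),
    min_delta_z = min(dz),
    max_delta_z = max(dz),
    range_delta_z = max(dz) - min(dz)
  )
}

#' @export
glance.axial_profile <- function(x, ...) z_separation_summary(x)
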