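# Regions of interest (picks): rectangles and simple polygons, stored in nm,
# serialized as YAML or JSON. Membership uses a half-open convention on
# rectangles (lower edges inclusive, upper exclusive) so tiled ROIs never
# double-count a localization.

#' Regions of interest
#'
#' `roi_rect()` builds an axis-aligned rectangular pick, `roi_polygon()` a
#' simple (non-self-intersecting) polygon from its vertices.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in nm.
#' @param id Label for the region.
#' @return A list of class `roi` with fields `id`, `kind`, `vertices` and
#'   `area` (in square micrometres).
#' @examples
#' roi_rect(0, 1000, 0, 1000)$area # 1 um^2
#' @export
roi_rect <- function(xmin, xmax, ymin, ymax, id = "roi") {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(
    list(
      id = id, kind = "rectangle",
      vertices = cbind(
        x = c(xmin, xmax, xmax, xmin),
        y = c(ymin, ymin, ymax, ymax)
      ),
      area = (xmax - xmin) * (ymax - ymin) * 1e-6
    ),
    class = "roi"
  )
}

#' @rdname roi_rect
#' @param x,y Polygon vertex coordinates in nm (not closed; the last vertex
#'   connects back to the first).
#' @export
roi_polygon <- function(x, y, id = "roi") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (.self_intersects(x, y)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  area <- abs(.signed_area(x, y)) * 1e-6
  if (area <= 0) stop("polygon has zero area", call. = FALSE)
  structure(
    list(id = id, kind = "polygon", vertices = cbind(x = x, y = y),
         area = area),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s'> %s, %d vertices, %.4g um^2\n",
              x$id, x$kind, nrow(x$vertices), x$area))
  invisible(x)
}

.signed_area <- function(x, y) {
  j <- c(seq_along(x)[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

.self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # shares a vertex with the closing edge
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(x[a[1]], y[a[1]], x[a[2]], y[a[2]], x[b[1]], y[b[1]])
      d2 <- cross(x[a[1]], y[a[1]], x[a[2]], y[a[2]], x[b[2]], y[b[2]])
      d3 <- cross(x[b[1]], y[b[1]], x[b[2]], y[b[2]], x[a[1]], y[a[1]])
      d4 <- cross(x[b[1]], y[b[1]], x[b[2]], y[b[2]], x[a[2]], y[a[2]])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# winding number point-in-polygon; boundary points are not guaranteed either way
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- integer(length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    upward <- vy[i] <= py & vy[j] > py
    downward <- vy[i] > py & vy[j] <= py
    is_left <- (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i])
    wn <- wn + ifelse(upward & is_left > 0, 1L, 0L) -
      ifelse(downward & is_left < 0, 1L, 0L)
  }
  wn != 0
}

#' Filter localizations (or sites) by a region of interest
#'
#' Rectangles use the half-open convention: a point on a lower/left edge is
#' inside, a point on an upper/right edge is outside. Polygons use the
#' winding-number rule.
#'
#' @param table A data frame with `x` and `y` columns (nm), e.g. a
#'   `loc_table` or a site map.
#' @param roi A [roi_rect()] or [roi_polygon()].
#' @return The filtered table (possibly empty), attributes preserved.
#' @export
filter_by_roi <- function(table, roi) {
  stopifnot(inherits(roi, "roi"))
  v <- roi$vertices
  keep <- if (roi$kind == "rectangle") {
    table$x >= min(v[, 1]) & table$x < max(v[, 1]) &
      table$y >= min(v[, 2]) & table$y < max(v[, 2])
  } else {
    .in_polygon(table$x, table$y, v[, 1], v[, 2])
  }
  out <- table[keep, , drop = FALSE]
  for (a in c("meta", "radius", "density", "field")) {
    if (!is.null(attr(table, a, exact = TRUE))) {
      attr(out, a) <- attr(table, a, exact = TRUE)
    }
  }
  out
}

#' Read and write region-of-interest picks
#'
#' Picks are stored as YAML or JSON documents with fields `id`, `kind`
#' (`rectangle`/`polygon`) and `vertices` (list of `[x, y]` nm pairs);
#' a file holds one ROI or a list of them.
#'
#' @param path File path (`.json` for JSON, otherwise YAML).
#' @return `read_roi()` returns an `roi` or list of them; `write_roi()`
#'   invisibly returns `path`.
#' @export
read_roi <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  parse1 <- function(d) {
    v <- d$vertices
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    v <- matrix(as.numeric(v), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
    if (identical(d$kind, "rectangle")) {
      roi_rect(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]),
               id = d$id %||% "roi")
    } else {
      roi_polygon(v[, 1], v[, 2], id = d$id %||% "roi")
    }
  }
  if (!is.null(doc$kind)) parse1(doc) else lapply(doc, parse1)
}

#' @rdname read_roi
#' @param roi An `roi` or a list of them.
#' @export
write_roi <- function(roi, path) {
  as_doc <- function(r) {
    list(id = r$id, kind = r$kind,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  }
  doc <- if (inherits(roi, "roi")) as_doc(roi) else lapply(roi, as_doc)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
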