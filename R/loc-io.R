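# Localization-table I/O. Coordinates are continuous nm in a field-anchored
# frame (origin at the lower-left corner of the field); acquisition metadata
# travels with the table as attributes and is serialized alongside the data.

#' Acquisition metadata
#'
#' Describes a DNA-PAINT acquisition: number of camera frames, exposure time,
#' effective pixel size, and the field of view in nm.
#'
#' @param n_frames Number of frames (>= 1).
#' @param exposure Exposure time per frame in seconds.
#' @param pixel_size Effective camera pixel size in nm (default 130).
#' @param field_width,field_height Field of view in nm.
#' @return A list of class `acquisition_meta`.
#' @examples
#' acquisition_meta(250000, 0.1, field_width = 5000, field_height = 5000)
#' @export
acquisition_meta <- function(n_frames, exposure, pixel_size = 130,
                             field_width = NULL, field_height = NULL) {
  stopifnot(n_frames >= 1, exposure > 0, pixel_size > 0)
  structure(
    list(
      n_frames = as.integer(n_frames), exposure = exposure,
      pixel_size = pixel_size,
      field_width = field_width, field_height = field_height
    ),
    class = "acquisition_meta"
  )
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(
    "<acquisition_meta> %d frames x %g s, pixel %g nm, field %s x %s nm\n",
    x$n_frames, x$exposure, x$pixel_size,
    format(x$field_width %||% NA), format(x$field_height %||% NA)
  ))
  invisible(x)
}

.required_loc_cols <- c("x", "y", "frame")

#' Build a localization table
#'
#' Validates a data frame of localizations and attaches acquisition
#' metadata. Input coordinates may be in camera pixels (`units = "px"`), in
#' which case they are converted to nm with the metadata's pixel size.
#'
#' @param data Data frame with at least columns `x`, `y`, `frame`
#'   (0-based frame index); optional `z`, `photons`, `sigma`, `channel`.
#' @param meta An [acquisition_meta()].
#' @param units `"nm"` (default) or `"px"` for the x/y/z coordinates.
#' @return A tibble of class `loc_table` with the metadata attached as the
#'   `meta` attribute, coordinates in nm.
#' @export
loc_table <- function(data, meta, units = c("nm", "px")) {
  units <- match.arg(units)
  stopifnot(inherits(meta, "acquisition_meta"))
  missing_cols <- setdiff(.required_loc_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("localization table is missing column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  # canonical column order and storage types
  canon <- intersect(c("x", "y", "z", "frame", "photons", "sigma",
                       "channel", "site"), names(out))
  out <- out[, c(canon, setdiff(names(out), canon))]
  out$frame <- as.integer(out$frame)
  for (col in intersect(c("x", "y", "z", "photons", "sigma"), names(out))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if (units == "px") {
    for (col in intersect(c("x", "y", "z", "sigma"), names(out))) {
      out[[col]] <- out[[col]] * meta$pixel_size
    }
  }
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    stop("localization coordinates must be finite", call. = FALSE)
  }
  if (any(out$frame < 0) || any(out$frame >= meta$n_frames)) {
    stop("frame indices must lie in [0, n_frames)", call. = FALSE)
  }
  attr(out, "meta") <- meta
  class(out) <- c("loc_table", class(out))
  out
}

#' Acquisition metadata of a localization table
#' @param table A `loc_table`.
#' @return The attached [acquisition_meta()].
#' @export
loc_meta <- function(table) {
  m <- attr(table, "meta", exact = TRUE)
  if (is.null(m)) stop("table carries no acquisition metadata", call. = FALSE)
  m
}

.meta_as_list <- function(meta) {
  m <- unclass(meta)
  m[!vapply(m, is.null, logical(1))]
}

.meta_from_list <- function(lst) {
  acquisition_meta(
    n_frames = lst$n_frames, exposure = lst$exposure,
    pixel_size = lst$pixel_size %||% 130,
    field_width = lst$field_width, field_height = lst$field_height
  )
}

#' Read and write localization tables
#'
#' Localization tables are stored either as CSV (comma-separated, header
#' row, '.' decimal; metadata in a `<path>.meta.yaml` sidecar) or as HDF5
#' with the table in a dataset named `locs` (one dataset per column, matching
#' the common SMLM localization-table dialect) and the metadata as HDF5
#' attributes, so third-party SMLM viewers can open the files. All
#' coordinates are written in nm.
#'
#' @param path File path; format is chosen by extension (`.h5`/`.hdf5` for
#'   HDF5, anything else is treated as CSV) unless `format` is given.
#' @param units Units of the coordinates in the file (`"nm"` or `"px"`).
#' @param meta An [acquisition_meta()]; if `NULL`, metadata is read from the
#'   sidecar/attributes.
#' @param format `"csv"` or `"hdf5"`.
#' @return `read_localizations()` returns a `loc_table`;
#'   `write_localizations()` invisibly returns `path`.
#' @examples
#' meta <- acquisition_meta(100, 0.1, field_width = 1000, field_height = 1000)
#' locs <- loc_table(data.frame(x = runif(5, 0, 1000), y = runif(5, 0, 1000),
#'                              frame = 0:4), meta)
#' f <- tempfile(fileext = ".csv")
#' write_localizations(locs, f)
#' read_localizations(f)
#' @export
read_localizations <- function(path, units = c("nm", "px"), meta = NULL,
                               format = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% .loc_format(path)
  if (format == "hdf5") {
    cols <- rhdf5::h5ls(path)
    grp <- cols$name[cols$group == "/locs"]
    data <- tibble::as_tibble(
      lapply(stats::setNames(grp, grp), function(col) {
        as.vector(rhdf5::h5read(path, paste0("locs/", col)))
      })
    )
    if (is.null(meta)) {
      m <- rhdf5::h5readAttributes(path, "locs")
      meta <- .meta_from_list(lapply(m, as.vector))
    }
  } else {
    data <- utils::read.csv(path)
    sidecar <- paste0(path, ".meta.yaml")
    if (is.null(meta)) {
      if (!file.exists(sidecar)) {
        stop("no metadata: supply `meta` or provide ", sidecar, call. = FALSE)
      }
      meta <- .meta_from_list(yaml::read_yaml(sidecar))
    }
  }
  loc_table(data, meta, units = units)
}

.loc_format <- function(path) {
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
}

#' @rdname read_localizations
#' @param table A `loc_table`.
#' @export
write_localizations <- function(table, path, format = NULL) {
  meta <- loc_meta(table)
  format <- format %||% .loc_format(path)
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "locs")
    for (col in names(table)) {
      rhdf5::h5write(table[[col]], path, paste0("locs/", col))
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "locs")
    for (nm in names(.meta_as_list(meta))) {
      rhdf5::h5writeAttribute(.meta_as_list(meta)[[nm]], gid, nm)
    }
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else {
    out <- tibble::as_tibble(table)
    # 17 significant digits guarantee bit-exact float64 round-trips,
    # which readr's default formatter does not
    for (col in names(out)) {
      if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    yaml::write_yaml(.meta_as_list(meta), paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Convert localization coordinates between pixels and nm
#'
#' Exact multiplication/division by the pixel size; converting px -> nm -> px
#' restores the input.
#'
#' @param x Numeric vector of coordinates.
#' @param pixel_size Pixel size in nm.
#' @return Converted coordinates.
#' @export
px_to_nm <- function(x, pixel_size = 130) x * pixel_size

#' @rdname px_to_nm
#' @export
nm_to_px <- function(x, pixel_size = 130) x / pixel_size

`%||%` <- function(a, b) if (is.null(a)) b else a
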