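#' Construct a localization table
#'
#' A localization table is the raw input of the pipeline: one row per fitted
#' single-molecule localization, with coordinates in nanometers in a common
#' nucleus frame.
#'
#' @param x_nm,y_nm numeric coordinates in nm.
#' @param frame integer acquisition frame (optional bookkeeping).
#' @param intensity arbitrary-unit brightness (optional bookkeeping).
#' @param uncertainty_nm per-localization precision estimate, >= 0.
#' @param channel channel label (e.g. \code{"nadna"}, \code{"A"}).
#' @param source_id optional integer provenance column used by the synthetic
#'   generator (focus id, 0 for background).
#' @return a \code{data.frame} of class \code{localization_table} with a
#'   \code{channel} attribute.
#' @export
localization_table <- function(x_nm, y_nm, frame = NULL, intensity = NULL,
                               uncertainty_nm = NULL, channel = "unknown",
                               source_id = NULL) {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n)
  if (n > 0 && (!all(is.finite(x_nm)) || !all(is.finite(y_nm))))
    stop("localization coordinates must be finite")
  if (!is.null(uncertainty_nm) && any(uncertainty_nm < 0, na.rm = TRUE))
    stop("uncertainty_nm must be >= 0")
  df <- data.frame(
    x_nm = as.numeric(x_nm),
    y_nm = as.numeric(y_nm),
    frame = if (is.null(frame)) rep(1L, n) else as.integer(frame),
    intensity = if (is.null(intensity)) rep(1, n) else as.numeric(intensity),
    uncertainty_nm = if (is.null(uncertainty_nm)) rep(NA_real_, n)
                     else as.numeric(uncertainty_nm)
  )
  if (!is.null(source_id)) df$source_id <- as.integer(source_id)
  attr(df, "channel") <- channel
  class(df) <- c("localization_table", "data.frame")
  df
}

loc_channel <- function(table) attr(table, "channel") %||% "unknown"

#' Read a localization table from CSV
#'
#' Supports the package's native header (\code{x_nm,y_nm,frame,intensity,
#' uncertainty_nm}) and ThunderSTORM-style headers (\code{x [nm]},
#' \code{y [nm]}, ...). Coordinates given in camera pixels can be converted
#' by supplying \code{pixel_size_nm}.
#'
#' @param path CSV file path.
#' @param dialect \code{"native"} or \code{"thunderstorm"}.
#' @param channel channel label to attach.
#' @param pixel_size_nm if supplied, x/y columns are multiplied by this
#'   factor (input assumed to be in camera pixels).
#' @return a \code{\link{localization_table}}.
#' @export
read_localizations <- function(path, dialect = c("native", "thunderstorm"),
                               channel = "unknown", pixel_size_nm = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  aliases <- if (dialect == "native") {
    list(x = "x_nm", y = "y_nm", frame = "frame", intensity = "intensity",
         uncertainty = "uncertainty_nm")
  } else {
    list(x = c("x [nm]", "x"), y = c("y [nm]", "y"), frame = "frame",
         intensity = c("intensity [photon]", "intensity"),
         uncertainty = c("uncertainty [nm]", "uncertainty_xy [nm]"))
  }
  pick <- function(cands) {
    hit <- cands[cands %in% names(df)]
    if (length(hit) == 0) NULL else df[[hit[1]]]
  }
  x <- pick(aliases$x); y <- pick(aliases$y)
  if (is.null(x) || is.null(y))
    stop("missing x/y columns; header was: ", paste(names(df), collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(x))) |
               !is.finite(suppressWarnings(as.numeric(y))))
  if (length(bad) > 0)
    stop("non-numeric coordinates at data row(s): ",
         paste(head(bad, 10), collapse = ", "))
  x <- as.numeric(x); y <- as.numeric(y)
  if (!is.null(pixel_size_nm)) {
    x <- x * pixel_size_nm
    y <- y * pixel_size_nm
  }
  localization_table(
    x, y,
    frame = pick(aliases$frame),
    intensity = pick(aliases$intensity),
    uncertainty_nm = pick(aliases$uncertainty),
    channel = channel,
    source_id = if ("source_id" %in% names(df)) df$source_id else NULL
  )
}

#' Write a localization table to CSV (native header)
#'
#' @param table a \code{\link{localization_table}}.
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Render a localization table into a fixed-pitch count image
#'
#' Pixels are half-open bins: a localization at x falls in column
#' \code{floor((x - x0)/pitch)} (0-based), so a point exactly on a bin edge
#' belongs to the higher pixel. Out-of-bounds localizations are dropped and
#' their count recorded in the \code{n_dropped} attribute.
#'
#' @param table a \code{\link{localization_table}}.
#' @param pitch_nm pixel pitch in nm (default 20).
#' @param bounds numeric \code{c(xmin, xmax, ymin, ymax)} in nm.
#' @return integer matrix of class \code{rendered_image} (rows = y, cols = x)
#'   with attributes \code{pitch_nm}, \code{origin_nm} and \code{n_dropped}.
#' @export
render <- function(table, pitch_nm = 20, bounds) {
  stopifnot(pitch_nm > 0, length(bounds) == 4)
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("inverted or empty bounds")
  nc <- ceiling((bounds[2] - bounds[1]) / pitch_nm)
  nr <- ceiling((bounds[4] - bounds[3]) / pitch_nm)
  j <- floor((table$x_nm - bounds[1]) / pitch_nm)   # 0-based col
  i <- floor((table$y_nm - bounds[3]) / pitch_nm)   # 0-based row
  ok <- j >= 0 & j < nc & i >= 0 & i < nr
  img <- matrix(0L, nr, nc)
  if (any(ok)) {
    lin <- i[ok] + 1L + j[ok] * nr
    tab <- tabulate(lin, nbins = nr * nc)
    img <- matrix(as.integer(tab), nr, nc)
  }
  attr(img, "pitch_nm") <- pitch_nm
  attr(img, "origin_nm") <- c(bounds[1], bounds[3])
  attr(img, "n_dropped") <- sum(!ok)
  class(img) <- c("rendered_image", class(img))
  img
}

grid_info <- function(x) {
  list(pitch_nm = attr(x, "pitch_nm"), origin_nm = attr(x, "origin_nm"),
       dim = dim(x))
}

# pixel centers in nm for 1-based (i = row, j = col) indices
pixel_centers <- function(i, j, pitch_nm, origin_nm) {
  cbind(x = origin_nm[1] + (j - 0.5) * pitch_nm,
        y = origin_nm[2] + (i - 0.5) * pitch_nm)
}

#' Build a nuclear ROI mask on the rendering grid
#'
#' Either rasterizes a polygon (pixel-center-inside rule) or loads a binary
#' mask image from PNG. The mask shares the grid (pitch, origin, shape) of
#' the images it will be applied to.
#'
#' @param polygon two-column matrix of vertices (nm), or \code{NULL}.
#' @param path path to an 8-bit PNG mask (nonzero = nuclear), or \code{NULL}.
#' @param pitch_nm pixel pitch in nm.
#' @param bounds \code{c(xmin, xmax, ymin, ymax)} in nm; required with
#'   \code{polygon}, and used to place a loaded mask in nucleus coordinates.
#' @return logical matrix of class \code{nucleus_roi} with \code{pitch_nm},
#'   \code{origin_nm} and (if available) \code{polygon} attributes.
#' @export
load_roi <- function(polygon = NULL, path = NULL, pitch_nm = 20, bounds) {
  if (is.null(polygon) == is.null(path))
    stop("supply exactly one of polygon or path")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3) stop("polygon needs >= 3 vertices")
    nc <- ceiling((bounds[2] - bounds[1]) / pitch_nm)
    nr <- ceiling((bounds[4] - bounds[3]) / pitch_nm)
    ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
    ctr <- pixel_centers(ij$i, ij$j, pitch_nm, c(bounds[1], bounds[3]))
    inside <- pracma::inpolygon(ctr[, 1], ctr[, 2],
                                polygon[, 1], polygon[, 2])
    mask <- matrix(inside, nr, nc)
    origin <- c(bounds[1], bounds[3])
  } else {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    mask <- px[rev(seq_len(nrow(px))), , drop = FALSE] > 0  # PNG rows top-down
    origin <- c(bounds[1], bounds[3])
  }
  if (!any(mask)) stop("empty ROI mask")
  attr(mask, "pitch_nm") <- pitch_nm
  attr(mask, "origin_nm") <- origin
  if (!is.null(polygon)) attr(mask, "polygon") <- polygon
  class(mask) <- c("nucleus_roi", class(mask))
  mask
}

#' Write a nuclear ROI mask as an 8-bit PNG
#'
#' @param roi a \code{nucleus_roi} mask.
#' @param path output PNG path.
#' @export
write_roi_mask <- function(roi, path) {
  m <- unclass(roi) * 1
  png::writePNG(m[rev(seq_len(nrow(m))), , drop = FALSE], path)
  invisible(path)
}

# default rendering bounds: ROI polygon bbox snapped to the pixel grid,
# padded by one pixel on each side
polygon_bounds <- function(poly, pitch_nm = 20) {
  xs <- range(poly[, 1]); ys <- range(poly[, 2])
  c(floor(xs[1] / pitch_nm - 1) * pitch_nm,
    ceiling(xs[2] / pitch_nm + 1) * pitch_nm,
    floor(ys[1] / pitch_nm - 1) * pitch_nm,
    ceiling(ys[2] / pitch_nm + 1) * pitch_nm)
}
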