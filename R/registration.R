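#' Match fiducial beads between two channels
#'
#' Pairs localizations by mutual nearest neighbors within a gating radius;
#' each bead is used at most once and non-mutual (ambiguous) beads are
#' discarded.
#'
#' @param ref reference-channel \code{\link{localization_table}}.
#' @param other source-channel \code{\link{localization_table}} to be
#'   mapped onto the reference.
#' @param radius_nm gating radius for a valid pair (default 500).
#' @return data.frame with columns \code{x_ref, y_ref, x_src, y_src, dist_nm}.
#' @export
match_beads <- function(ref, other, radius_nm = 500) {
  if (nrow(ref) == 0 || nrow(other) == 0) stop("empty bead table")
  dx <- outer(ref$x_nm, other$x_nm, "-")
  dy <- outer(ref$y_nm, other$y_nm, "-")
  d <- sqrt(dx^2 + dy^2)
  nn_ro <- apply(d, 1, which.min)           # for each ref, nearest other
  nn_or <- apply(d, 2, which.min)           # for each other, nearest ref
  i <- seq_len(nrow(ref))
  mutual <- nn_or[nn_ro] == i
  dmin <- d[cbind(i, nn_ro)]
  keep <- mutual & dmin <= radius_nm
  data.frame(
    x_ref = ref$x_nm[keep], y_ref = ref$y_nm[keep],
    x_src = other$x_nm[nn_ro[keep]], y_src = other$y_nm[nn_ro[keep]],
    dist_nm = dmin[keep]
  )
}

n_poly_terms <- function(degree) (degree + 1) * (degree + 2) / 2

# bivariate monomial design matrix on centered/scaled coordinates
poly_design <- function(x, y, degree, scale) {
  xs <- (x - scale$cx) / scale$s
  ys <- (y - scale$cy) / scale$s
  cols <- list()
  for (d in 0:degree)
    for (a in d:0)
      cols[[length(cols) + 1L]] <- xs^a * ys^(d - a)
  do.call(cbind, cols)
}

#' Fit a polynomial chromatic/offset mapping from matched bead pairs
#'
#' Least-squares fit of bivariate polynomial surfaces x'(x, y), y'(x, y)
#' taking source-channel coordinates to the reference channel; this is the
#' morph-type mapping conventionally fitted to multicolor fiducial bead
#' fields. Coordinates are internally centered and scaled for conditioning.
#' With >= 20 pairs a deterministic 20\% split (every fifth pair) is held
#' out to report an out-of-sample residual; returned coefficients are
#' refitted on all pairs.
#'
#' @param pairs data.frame from \code{\link{match_beads}}.
#' @param degree polynomial degree (default 3, full bivariate terms).
#' @return object of class \code{polynomial_map} with coefficient vectors,
#'   the coordinate scaling, \code{rms_nm} (training residual RMS over both
#'   axes, i.e. RMS 2D distance) and \code{heldout_rms_nm} (NA if < 20
#'   pairs).
#' @export
fit_map <- function(pairs, degree = 3) {
  stopifnot(degree >= 1)
  p <- n_poly_terms(degree)
  if (nrow(pairs) < p)
    stop("need >= ", p, " pairs for degree ", degree, "; have ", nrow(pairs))
  scale <- list(cx = mean(pairs$x_src), cy = mean(pairs$y_src),
                s = max(sd(pairs$x_src), sd(pairs$y_src), 1))
  solve_axes <- function(rows) {
    X <- poly_design(pairs$x_src[rows], pairs$y_src[rows], degree, scale)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient bead design (collinear beads); need a spread field")
    list(bx = qr.coef(qrX, pairs$x_ref[rows]),
         by = qr.coef(qrX, pairs$y_ref[rows]))
  }
  rms_on <- function(fit, rows) {
    X <- poly_design(pairs$x_src[rows], pairs$y_src[rows], degree, scale)
    rx <- pairs$x_ref[rows] - X %*% fit$bx
    ry <- pairs$y_ref[rows] - X %*% fit$by
    sqrt(mean(rx^2 + ry^2))
  }
  n <- nrow(pairs)
  heldout_rms <- NA_real_
  if (n >= 20) {
    test <- seq(5, n, by = 5)
    train <- setdiff(seq_len(n), test)
    if (length(train) >= p)
      heldout_rms <- rms_on(solve_axes(train), test)
  }
  fit <- solve_axes(seq_len(n))
  structure(list(
    degree = degree, coef_x = fit$bx, coef_y = fit$by, scale = scale,
    rms_nm = rms_on(fit, seq_len(n)), heldout_rms_nm = heldout_rms,
    n_beads = n
  ), class = "polynomial_map")
}

#' Apply a fitted polynomial map to a localization table
#'
#' Transforms coordinates only; every other field (frame, intensity,
#' uncertainty, provenance) and the record count are preserved.
#'
#' @param map a \code{polynomial_map} from \code{\link{fit_map}}.
#' @param table a \code{\link{localization_table}} in the map's source
#'   channel coordinates.
#' @return the transformed \code{localization_table}.
#' @export
apply_map <- function(map, table) {
  stopifnot(inherits(map, "polynomial_map"))
  if (nrow(table) == 0) return(table)
  X <- poly_design(table$x_nm, table$y_nm, map$degree, map$scale)
  out <- table
  out$x_nm <- as.numeric(X %*% map$coef_x)
  out$y_nm <- as.numeric(X %*% map$coef_y)
  out
}

#' Serialize / restore a polynomial map as JSON
#'
#' @param map a \code{polynomial_map}.
#' @param path JSON file path.
#' @export
write_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coef_x <- as.numeric(m$coef_x)
  m$coef_y <- as.numeric(m$coef_y)
  structure(m, class = "polynomial_map")
}

#' @export
print.polynomial_map <- function(x, ...) {
  cat(sprintf(
    "polynomial_map: degree %d, %d beads, residual RMS %.2f nm (held-out %s)\n",
    x$degree, x$n_beads, x$rms_nm,
    if (is.na(x$heldout_rms_nm)) "n/a" else sprintf("%.2f nm", x$heldout_rms_nm)))
  invisible(x)
}
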