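#' Center-of-mass distances between colocalized markers
#'
#' With a reference channel (\code{nadna}), emits one sample per reference
#' focus that overlaps at least one cluster of each marker: the Euclidean
#' distance between the centers of mass of the nearest A-B cluster pair
#' within that focus. Without a reference channel (dual-label calibration
#' data), A and B clusters are paired by mutual nearest neighbors of their
#' centers of mass within \code{max_dist_nm}.
#'
#' @param chA,chB marker-channel \code{cluster_set}s on one grid.
#' @param nadna optional reference-channel \code{cluster_set}.
#' @param max_dist_nm pairing gate used in the calibration (no-reference)
#'   mode (default 500).
#' @param nucleus optional nucleus id recorded per sample.
#' @return data.frame with columns \code{nucleus}, \code{focus_id}
#'   (NA in calibration mode), \code{d_nm}.
#' @export
pair_distances <- function(chA, chB, nadna = NULL, max_dist_nm = 500,
                           nucleus = NA) {
  comA <- t(vapply(chA$clusters, `[[`, numeric(2), "com_nm"))
  comB <- t(vapply(chB$clusters, `[[`, numeric(2), "com_nm"))
  empty <- data.frame(nucleus = character(0), focus_id = integer(0),
                      d_nm = numeric(0))
  if (length(chA$clusters) == 0 || length(chB$clusters) == 0) return(empty)
  if (!is.null(nadna)) {
    mA <- cluster_union_mask(chA)
    mB <- cluster_union_mask(chB)
    rows <- list()
    for (cl in nadna$clusters) {
      inA <- which(vapply(chA$clusters,
                          function(a) any(a$px %in% cl$px), logical(1)))
      inB <- which(vapply(chB$clusters,
                          function(b) any(b$px %in% cl$px), logical(1)))
      if (length(inA) == 0 || length(inB) == 0) next
      d <- outer(seq_along(inA), seq_along(inB), function(i, j) {
        sqrt((comA[inA[i], 1] - comB[inB[j], 1])^2 +
             (comA[inA[i], 2] - comB[inB[j], 2])^2)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus = nucleus, focus_id = cl$id, d_nm = min(d))
    }
    if (length(rows) == 0) return(empty)
    do.call(rbind, rows)
  } else {
    dx <- outer(comA[, 1], comB[, 1], "-")
    dy <- outer(comA[, 2], comB[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    nn_ab <- apply(d, 1, which.min)
    nn_ba <- apply(d, 2, which.min)
    i <- seq_len(nrow(comA))
    mutual <- nn_ba[nn_ab] == i
    dmin <- d[cbind(i, nn_ab)]
    keep <- mutual & dmin <= max_dist_nm
    if (!any(keep)) return(empty)
    data.frame(nucleus = nucleus, focus_id = NA_integer_,
               d_nm = dmin[keep])
  }
}

gauss_curve <- function(x, amp, center, sigma)
  amp * exp(-(x - center)^2 / (2 * sigma^2))

#' Fit the intrafocus distance histogram with one or two Gaussians
#'
#' Bins the center-of-mass distance samples (default 20 nm bins, one
#' rendering pixel) and least-squares fits a single free Gaussian. A
#' two-component model is also fitted following the calibration-anchored
#' procedure: component 1 is fixed at the dual-label calibration standard
#' (center 135 nm, FWHM 75 nm) with only its area free, first alone, then
#' a second fully free Gaussian is fitted to the remaining histogram, and
#' finally both are refined jointly (component-1 center/width still
#' fixed). The single model is kept unless the double model improves the
#' AIC by at least \code{ic_margin}.
#'
#' @param d_nm numeric distance samples, or the data.frame from
#'   \code{\link{pair_distances}}.
#' @param bin_width_nm histogram bin width (default 20).
#' @param min_samples refusal floor (default 20; >= 50 recommended).
#' @param calib_center_nm,calib_fwhm_nm the fixed calibration component
#'   (defaults 135 and 75).
#' @param ic_margin AIC improvement required to prefer the double model
#'   (default 6).
#' @param model \code{"auto"} (information-criterion selection,
#'   default), \code{"single"} (force the single free Gaussian, e.g. when
#'   fitting the calibration standard itself), or \code{"double"}.
#' @return object of class \code{association_fit}: \code{model}
#'   (\code{"single"} or \code{"double"}), \code{components} data.frame
#'   (center_nm, fwhm_nm, area), \code{rss}, \code{aic_single},
#'   \code{aic_double}, histogram (\code{breaks}, \code{counts},
#'   \code{mids}), \code{n}.
#' @export
fit_association <- function(d_nm, bin_width_nm = 20, min_samples = 20,
                            calib_center_nm = 135, calib_fwhm_nm = 75,
                            ic_margin = 6,
                            model = c("auto", "single", "double")) {
  model <- match.arg(model)
  if (is.data.frame(d_nm)) d_nm <- d_nm$d_nm
  d_nm <- d_nm[is.finite(d_nm)]
  if (length(d_nm) < min_samples)
    stop("need >= ", min_samples, " distance samples; have ", length(d_nm))
  breaks <- seq(0, (max(d_nm) %/% bin_width_nm + 1) * bin_width_nm,
                by = bin_width_nm)
  h <- graphics::hist(d_nm, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  n <- length(y)

  # single free Gaussian
  mu0 <- sum(x * y) / sum(y)
  s0 <- max(sqrt(sum(y * (x - mu0)^2) / sum(y)), bin_width_nm / 2)
  fit1 <- minpack.lm::nlsLM(
    y ~ gauss_curve(x, amp, center, sigma),
    start = list(amp = max(y), center = mu0, sigma = s0),
    lower = c(0, 0, bin_width_nm / 4),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p1 <- coef(fit1)
  rss1 <- sum(residuals(fit1)^2)
  aic1 <- n * log(rss1 / n) + 2 * 3

  # double model, calibration component fixed in center and width
  fit2 <- NULL
  rss2 <- Inf
  aic2 <- Inf
  s_cal <- fwhm_to_sigma(calib_fwhm_nm)
  g_cal <- exp(-(x - calib_center_nm)^2 / (2 * s_cal^2))
  a1_init <- max(sum(g_cal * y) / sum(g_cal^2), 0)    # LS area, stage 1
  resid1 <- pmax(y - a1_init * g_cal, 0)
  mu2_init <- if (sum(resid1) > 0) sum(x * resid1) / sum(resid1) else mu0
  s2_init <- if (sum(resid1) > 0)
    max(sqrt(sum(resid1 * (x - mu2_init)^2) / sum(resid1)),
        bin_width_nm / 2) else s0
  if (model != "single") {
    fit2 <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * g_cal + gauss_curve(x, a2, mu2, s2),
        start = list(a1 = a1_init, a2 = max(resid1),
                     mu2 = mu2_init, s2 = s2_init),
        lower = c(0, 0, 0, bin_width_nm / 4),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      p2 <- coef(fit2)
      rss2 <- sum(residuals(fit2)^2)
      aic2 <- n * log(rss2 / n) + 2 * 4
    }
    if (model == "double" && is.null(fit2))
      stop("double-Gaussian fit did not converge")
  }

  use_double <- switch(model,
    auto = is.finite(aic2) && (aic1 - aic2) >= ic_margin,
    single = FALSE,
    double = TRUE)
  if (use_double) {
    comp <- data.frame(
      component = c("calibration", "free"),
      center_nm = c(calib_center_nm, p2[["mu2"]]),
      fwhm_nm = c(calib_fwhm_nm, sigma_to_fwhm(p2[["s2"]])),
      area = c(p2[["a1"]] * s_cal * sqrt(2 * pi),
               p2[["a2"]] * p2[["s2"]] * sqrt(2 * pi)))
    rss <- rss2
  } else {
    comp <- data.frame(
      component = "single",
      center_nm = p1[["center"]],
      fwhm_nm = sigma_to_fwhm(p1[["sigma"]]),
      area = p1[["amp"]] * p1[["sigma"]] * sqrt(2 * pi))
    rss <- rss1
  }
  structure(list(
    model = if (use_double) "double" else "single",
    components = comp, rss = rss,
    aic_single = aic1, aic_double = aic2,
    bin_width_nm = bin_width_nm, breaks = breaks, counts = y, mids = x,
    n = length(d_nm),
    calib_center_nm = calib_center_nm, calib_fwhm_nm = calib_fwhm_nm
  ), class = "association_fit")
}

# fitted 1D curve of an association_fit at positions x (in counts units)
association_curve <- function(fit, x) {
  total <- numeric(length(x))
  for (k in seq_len(nrow(fit$components))) {
    s <- fwhm_to_sigma(fit$components$fwhm_nm[k])
    amp <- fit$components$area[k] / (s * sqrt(2 * pi))
    total <- total + gauss_curve(x, amp, fit$components$center_nm[k], s)
  }
  total
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("association_fit: %s model, n = %d, bin %g nm\n",
              x$model, x$n, x$bin_width_nm))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Classify an intrafocus association from its fitted distribution
#'
#' A single-Gaussian fit centered within the calibration window
#' 135 +/- 37.5 nm is an intimate (proximal, potentially interacting)
#' association; a single fit centered beyond 180 nm is distal (same focus,
#' spatially separated); a selected double model is mixed. Single centers
#' in the uncovered interval (172.5, 180] nm, or below the calibration
#' window, are reported as indeterminate rather than forced to a side.
#'
#' @param fit an \code{association_fit}.
#' @return object of class \code{association_class} with \code{label} in
#'   \{intimate, distal, mixed, indeterminate\} and the supporting fit.
#' @export
classify_association <- function(fit) {
  stopifnot(inherits(fit, "association_fit"))
  lo <- fit$calib_center_nm - 37.5
  hi <- fit$calib_center_nm + 37.5
  label <- if (fit$model == "double") "mixed" else {
    ctr <- fit$components$center_nm[1]
    if (ctr >= lo && ctr <= hi) "intimate"
    else if (ctr > 180) "distal"
    else "indeterminate"
  }
  structure(list(label = label, fit = fit), class = "association_class")
}

#' @export
print.association_class <- function(x, ...) {
  cat("association:", x$label, "\n")
  invisible(x)
}

#' Render a fitted association distribution as a contoured 2D map
#'
#' Extrapolates the fitted 1D distance/intensity curve into a 2D heat map:
#' at each distance (column) a perpendicular Gaussian profile is drawn
#' whose integrated area equals the fitted intensity at that distance, so
#' the column-wise integral reproduces the 1D curve and the image integral
#' equals the total fitted area. The perpendicular FWHM defaults to each
#' component's own fitted FWHM.
#'
#' @param fit an \code{association_fit}.
#' @param extent_nm distance-axis extent (default: histogram extent).
#' @param pitch_nm map pixel pitch (default the histogram bin width).
#' @param perpendicular_fwhm_nm overriding perpendicular FWHM (applied to
#'   all components), or NULL for per-component defaults.
#' @return numeric matrix (rows = perpendicular axis, cols = distance)
#'   with attributes \code{pitch_nm} and \code{x_nm} (column centers).
#' @export
render_distribution_map <- function(fit, extent_nm = NULL, pitch_nm = NULL,
                                    perpendicular_fwhm_nm = NULL) {
  stopifnot(inherits(fit, "association_fit"))
  pitch_nm <- pitch_nm %||% fit$bin_width_nm
  extent_nm <- extent_nm %||% max(fit$breaks)
  if (extent_nm <= 0 || pitch_nm <= 0) stop("non-positive extent or pitch")
  xc <- seq(pitch_nm / 2, extent_nm, by = pitch_nm)
  half <- extent_nm / 2
  yc <- seq(-half + pitch_nm / 2, half, by = pitch_nm)
  img <- matrix(0, nrow = length(yc), ncol = length(xc))
  for (k in seq_len(nrow(fit$components))) {
    s <- fwhm_to_sigma(fit$components$fwhm_nm[k])
    amp <- fit$components$area[k] / (s * sqrt(2 * pi))
    ix <- gauss_curve(xc, amp, fit$components$center_nm[k], s)
    sp <- fwhm_to_sigma(perpendicular_fwhm_nm %||% fit$components$fwhm_nm[k])
    prof <- exp(-yc^2 / (2 * sp^2))
    prof <- prof / (sum(prof) * pitch_nm)   # unit area on the grid
    img <- img + outer(prof, ix)
  }
  attr(img, "pitch_nm") <- pitch_nm
  attr(img, "x_nm") <- xc
  img
}
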