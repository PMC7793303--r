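#' Configuration for the synthetic nucleus generator
#'
#' Describes an early-mid S-phase nucleus as imaged in 2D SMLM: an
#' elliptical nuclear ROI containing on the order of a hundred spatially
#' distinct nascent-DNA (naDNA) replication foci, a subset of which carry
#' single protein puncta in marker channels A and/or B at configurable
#' co-occupancy fractions. Marker puncta are displaced from their focus
#' center by a radial offset drawn from a Gaussian truncated at zero with
#' uniform angle (default center 80 nm, FWHM 75 nm, keeping the punctum
#' overlapping the larger focus as observed in replicating nuclei; the
#' dual-label calibration geometry with its 135 nm standard lives in
#' \code{\link{generate_calibration_foci}}). Localization counts per
#' punctum are Poisson
#' (blinking multiplicity); per-channel localization precision defaults to
#' 8 nm for the red/blue-like channels and 16 nm for the green-like one.
#'
#' @param nucleus_axes_um ellipse semi-axes in micrometers (default 5 x 4).
#' @param n_foci number of naDNA foci (default 100).
#' @param focus_sigma_nm Gaussian spatial spread of a naDNA focus (default 70).
#' @param punctum_sigma_nm spread of a protein punctum (default 40).
#' @param locs_per_focus,locs_per_punctum mean localization counts (Poisson).
#' @param precision_nm named per-channel localization precision in nm.
#' @param background_density non-focal localizations per square micrometer
#'   per channel (default 2).
#' @param cooccupancy named fractions of naDNA foci carrying marker A only,
#'   B only, or both (\code{A}, \code{B}, \code{AB}); the remainder carry
#'   neither. Must be in [0, 1] and sum to <= 1.
#' @param offset_model per-marker radial offset distribution, each a list
#'   with \code{center_nm} and \code{fwhm_nm}.
#' @param random_puncta named counts of additional marker puncta placed
#'   uniformly at random in the ROI, independent of any focus (0 = none);
#'   used to emulate random (enrichment 1) marker placement.
#' @param min_spacing_nm minimum distance between focus centers (default
#'   300, keeping foci spatially distinct at 20 nm rendering).
#' @param chromatic_shift_nm optional named list of per-channel c(dx, dy)
#'   offsets applied to non-reference channels (uncorrected chromatic
#'   error); NULL = channels already registered.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(nucleus_axes_um = c(5, 4),
                       n_foci = 100,
                       focus_sigma_nm = 70,
                       punctum_sigma_nm = 40,
                       locs_per_focus = 400,
                       locs_per_punctum = 80,
                       precision_nm = c(nadna = 8, A = 8, B = 16),
                       background_density = 2,
                       cooccupancy = c(A = 0.15, B = 0.15, AB = 0.05),
                       offset_model = list(
                         A = list(center_nm = 80, fwhm_nm = 75),
                         B = list(center_nm = 80, fwhm_nm = 75)),
                       random_puncta = c(A = 0, B = 0),
                       min_spacing_nm = 300,
                       chromatic_shift_nm = NULL) {
  cfg <- list(nucleus_axes_um = nucleus_axes_um, n_foci = n_foci,
              focus_sigma_nm = focus_sigma_nm,
              punctum_sigma_nm = punctum_sigma_nm,
              locs_per_focus = locs_per_focus,
              locs_per_punctum = locs_per_punctum,
              precision_nm = precision_nm,
              background_density = background_density,
              cooccupancy = cooccupancy, offset_model = offset_model,
              random_puncta = random_puncta,
              min_spacing_nm = min_spacing_nm,
              chromatic_shift_nm = chromatic_shift_nm)
  stopifnot(length(nucleus_axes_um) == 2, all(nucleus_axes_um > 0),
            n_foci >= 0, focus_sigma_nm > 0, punctum_sigma_nm > 0,
            locs_per_focus >= 0, locs_per_punctum >= 0,
            all(precision_nm >= 0), background_density >= 0,
            min_spacing_nm >= 0)
  co <- cooccupancy[c("A", "B", "AB")]
  if (any(is.na(co))) stop("cooccupancy needs named fractions A, B, AB")
  if (any(co < 0) || any(co > 1) || sum(co) > 1 + 1e-12)
    stop("co-occupancy fractions must be in [0,1] and sum to <= 1")
  for (m in names(offset_model))
    stopifnot(offset_model[[m]]$center_nm >= 0, offset_model[[m]]$fwhm_nm > 0)
  class(cfg) <- "sim_config"
  cfg
}

# focus centers by dart throwing with a minimum pairwise spacing
place_focus_centers <- function(n, a_nm, b_nm, min_spacing_nm,
                                max_attempts = 20000) {
  pts <- matrix(numeric(0), ncol = 2)
  attempts <- 0
  # keep centers one spacing inside the boundary so whole foci stay in-ROI
  fa <- max(a_nm - min_spacing_nm, a_nm * 0.5)
  fb <- max(b_nm - min_spacing_nm, b_nm * 0.5)
  while (nrow(pts) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("nucleus too small to host ", n, " foci at ",
           min_spacing_nm, " nm spacing")
    p <- runif_in_ellipse(1, fa, fb)
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_spacing_nm^2)
      pts <- rbind(pts, p)
  }
  pts
}

# localizations for one punctum: blinking multiplicity is Poisson, spatial
# spread is the punctum size convolved with the localization precision
punctum_locs <- function(center, mean_locs, sigma_nm, precision_nm, id) {
  n <- rpois(1, mean_locs)
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), id = integer(0)))
  s <- sqrt(sigma_nm^2 + precision_nm^2)
  data.frame(x = rnorm(n, center[1], s), y = rnorm(n, center[2], s),
             id = rep(id, n))
}

finalize_channel <- function(df, channel, precision_nm, shift = NULL) {
  if (!is.null(shift)) {
    df$x <- df$x + shift[1]
    df$y <- df$y + shift[2]
  }
  n <- nrow(df)
  localization_table(
    df$x, df$y,
    frame = if (n) sample.int(2000, n, replace = TRUE) else integer(0),
    intensity = if (n) round(rexp(n, 1 / 500)) + 50 else numeric(0),
    uncertainty_nm = rep(precision_nm, n),
    channel = channel, source_id = df$id
  )
}

#' Generate one synthetic nucleus with planted ground truth
#'
#' Emits per-channel localization tables (\code{nadna}, \code{A}, \code{B}),
#' the elliptical ROI polygon, and a ground-truth manifest recording every
#' focus center, its marker pattern and the planted intrafocus offsets.
#' Every localization carries a \code{source_id} tracing it to a focus
#' (or 0 for background).
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional RNG seed; fixed seed gives identical output.
#' @return list with \code{tables} (named localization tables),
#'   \code{roi_polygon} (nm), and \code{truth} (per-focus data.frame:
#'   id, x/y center, pattern, per-marker planted offset).
#' @export
generate_nucleus <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  a <- config$nucleus_axes_um[1] * 1000
  b <- config$nucleus_axes_um[2] * 1000
  poly <- ellipse_polygon(a, b)
  centers <- place_focus_centers(config$n_foci, a, b, config$min_spacing_nm)
  co <- config$cooccupancy[c("A", "B", "AB")]
  patterns <- if (config$n_foci > 0)
    sample(c("A", "B", "AB", "none"), config$n_foci, replace = TRUE,
           prob = c(co, 1 - sum(co)))
  else character(0)

  truth <- data.frame(
    id = seq_len(config$n_foci),
    x_nm = if (config$n_foci) centers[, 1] else numeric(0),
    y_nm = if (config$n_foci) centers[, 2] else numeric(0),
    pattern = patterns,
    offset_A_nm = rep(NA_real_, config$n_foci),
    offset_B_nm = rep(NA_real_, config$n_foci)
  )

  parts <- list(nadna = list(), A = list(), B = list())

  for (k in seq_len(config$n_foci)) {
    parts$nadna[[length(parts$nadna) + 1L]] <- punctum_locs(
      centers[k, ], config$locs_per_focus, config$focus_sigma_nm,
      config$precision_nm[["nadna"]], k)
    for (m in c("A", "B")) {
      if (patterns[k] %in% c(m, "AB")) {
        om <- config$offset_model[[m]]
        d <- rtrunc_radial(1, om$center_nm, om$fwhm_nm)
        th <- runif(1, 0, 2 * pi)
        truth[[paste0("offset_", m, "_nm")]][k] <- d
        pc <- centers[k, ] + d * c(cos(th), sin(th))
        parts[[m]][[length(parts[[m]]) + 1L]] <- punctum_locs(
          pc, config$locs_per_punctum, config$punctum_sigma_nm,
          config$precision_nm[[m]], k)
      }
    }
  }

  # marker puncta independent of any focus (random placement, enrichment 1)
  for (m in c("A", "B")) {
    nrand <- config$random_puncta[[m]] %||% 0
    if (nrand > 0) {
      pos <- runif_in_ellipse(nrand, a, b)
      for (r in seq_len(nrand))
        parts[[m]][[length(parts[[m]]) + 1L]] <- punctum_locs(
          pos[r, ], config$locs_per_punctum, config$punctum_sigma_nm,
          config$precision_nm[[m]], 0L)
    }
  }

  # uniform background localizations per channel
  area_um2 <- pi * (a / 1000) * (b / 1000)
  for (nm in names(parts)) {
    nbg <- rpois(1, config$background_density * area_um2)
    if (nbg > 0) {
      bg <- runif_in_ellipse(nbg, a, b)
      parts[[nm]][[length(parts[[nm]]) + 1L]] <-
        data.frame(x = bg[, 1], y = bg[, 2], id = 0L)
    }
  }

  empty <- data.frame(x = numeric(0), y = numeric(0), id = integer(0))
  ch <- lapply(parts, function(p)
    if (length(p)) do.call(rbind, p) else empty)

  shifts <- config$chromatic_shift_nm
  tables <- list(
    nadna = finalize_channel(ch$nadna, "nadna",
                             config$precision_nm[["nadna"]],
                             shifts$nadna),
    A = finalize_channel(ch$A, "A", config$precision_nm[["A"]], shifts$A),
    B = finalize_channel(ch$B, "B", config$precision_nm[["B"]], shifts$B)
  )
  list(tables = tables, roi_polygon = poly, truth = truth, config = config)
}

#' Generate dual-label calibration foci
#'
#' Emulates the calibration experiment in which one protein species is
#' labeled in two colors simultaneously: each focus emits a channel-A
#' punctum and a channel-B punctum whose center is displaced by a radial
#' offset drawn from a Gaussian truncated at zero (default center 135 nm,
#' FWHM 75 nm) with uniform angle. Foci are laid out on a jittered grid so
#' segmentation cannot merge neighbors. Defaults describe a bright
#' accumulation-type calibration target (300 localizations per punctum)
#' pooled over 150 foci, enough that the sampling error of the fitted
#' width stays below a few nanometers.
#'
#' @param n_foci number of calibration foci (>= 50; default 150).
#' @param offset_center_nm,offset_fwhm_nm radial offset distribution.
#' @param punctum_sigma_nm punctum spread (default 40).
#' @param locs_per_punctum mean localization count per punctum.
#' @param precision_nm length-2 per-channel precision (A, B).
#' @param spacing_nm grid spacing between foci (default 1500).
#' @param seed optional RNG seed.
#' @return list with \code{tables} (channels \code{A}, \code{B}),
#'   \code{roi_polygon}, and \code{truth} (planted offsets per focus).
#' @export
generate_calibration_foci <- function(n_foci = 150,
                                      offset_center_nm = 135,
                                      offset_fwhm_nm = 75,
                                      punctum_sigma_nm = 40,
                                      locs_per_punctum = 300,
                                      precision_nm = c(A = 8, B = 8),
                                      spacing_nm = 1500,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(sqrt(n_foci))
  gx <- (seq_len(side) - 0.5) * spacing_nm
  grid <- as.matrix(expand.grid(x = gx, y = gx))[seq_len(n_foci), , drop = FALSE]
  grid <- grid + matrix(runif(2 * n_foci, -spacing_nm / 8, spacing_nm / 8),
                        ncol = 2)
  d <- rtrunc_radial(n_foci, offset_center_nm, offset_fwhm_nm)
  th <- runif(n_foci, 0, 2 * pi)
  A <- B <- data.frame(x = numeric(0), y = numeric(0), id = integer(0))
  for (k in seq_len(n_foci)) {
    A <- rbind(A, punctum_locs(grid[k, ], locs_per_punctum,
                               punctum_sigma_nm, precision_nm[[1]], k))
    B <- rbind(B, punctum_locs(grid[k, ] + d[k] * c(cos(th[k]), sin(th[k])),
                               locs_per_punctum, punctum_sigma_nm,
                               precision_nm[[2]], k))
  }
  ext <- side * spacing_nm
  poly <- cbind(x = c(-200, ext + 200, ext + 200, -200),
                y = c(-200, -200, ext + 200, ext + 200))
  list(
    tables = list(A = finalize_channel(A, "A", precision_nm[[1]]),
                  B = finalize_channel(B, "B", precision_nm[[2]])),
    roi_polygon = poly,
    truth = data.frame(id = seq_len(n_foci), x_nm = grid[, 1],
                       y_nm = grid[, 2], offset_nm = d, angle = th)
  )
}

#' Generate a synthetic fiducial bead field in two channels
#'
#' Reference-channel bead positions are uniform in the field with a minimum
#' pairwise spacing (so matching is unambiguous); the second channel is the
#' distorted reference plus Gaussian localization noise.
#'
#' @param n_beads number of beads.
#' @param field_nm field extent \code{c(width, height)} in nm.
#' @param distortion \code{NULL} (identity), a length-2 numeric shift in nm,
#'   or a function \code{(x, y) -> list(x, y)} applying an arbitrary
#'   (e.g. polynomial) chromatic distortion.
#' @param precision_nm per-axis Gaussian localization noise of the source
#'   channel relative to the reference (default 5). The reference-channel
#'   bead positions define the target frame, so the noise of both fits is
#'   folded into this one relative scale.
#' @param min_spacing_nm minimum bead separation (default 1500).
#' @param seed optional RNG seed.
#' @return list with \code{ref} and \code{other} localization tables and
#'   \code{truth} (noise-free reference positions).
#' @export
generate_bead_field <- function(n_beads, field_nm = c(40000, 40000),
                                distortion = NULL, precision_nm = 5,
                                min_spacing_nm = 1500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_beads * (min_spacing_nm^2) > 0.35 * prod(field_nm))
    stop("beads too dense for unambiguous matching at this spacing")
  pts <- matrix(numeric(0), ncol = 2)
  attempts <- 0
  while (nrow(pts) < n_beads) {
    attempts <- attempts + 1
    if (attempts > 50000) stop("could not place beads at requested spacing")
    p <- c(runif(1, 0, field_nm[1]), runif(1, 0, field_nm[2]))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_spacing_nm^2)
      pts <- rbind(pts, p)
  }
  dist_fun <- if (is.null(distortion)) {
    function(x, y) list(x = x, y = y)
  } else if (is.numeric(distortion) && length(distortion) == 2) {
    function(x, y) list(x = x + distortion[1], y = y + distortion[2])
  } else if (is.function(distortion)) {
    distortion
  } else stop("distortion must be NULL, a length-2 shift, or a function")
  dd <- dist_fun(pts[, 1], pts[, 2])
  noise <- function(n) rnorm(n, 0, precision_nm)
  ref <- localization_table(pts[, 1], pts[, 2],
                            uncertainty_nm = rep(0, n_beads),
                            channel = "ref")
  other <- localization_table(dd$x + noise(n_beads), dd$y + noise(n_beads),
                              uncertainty_nm = rep(precision_nm, n_beads),
                              channel = "other")
  list(ref = ref, other = other, truth = pts)
}

#' Generate a multi-condition study dataset on disk
#'
#' Writes per-nucleus, per-channel localization CSVs, ROI masks (PNG on the
#' 20 nm grid) and a JSON manifest recording every planted parameter and
#' per-nucleus seed; the layout is what \code{\link{run_study}} consumes.
#'
#' @param conditions named list of \code{\link{sim_config}} objects, one
#'   per condition (e.g. control and treated).
#' @param n_nuclei nuclei per condition.
#' @param dir output directory.
#' @param seed run seed; per-nucleus seeds are derived deterministically.
#' @param pitch_nm rendering pitch for the ROI masks (default 20).
#' @param overwrite refuse to write into an existing directory unless TRUE.
#' @return path of the manifest JSON, invisibly.
#' @export
generate_study <- function(conditions, n_nuclei, dir, seed = 1,
                           pitch_nm = 20, overwrite = FALSE) {
  stopifnot(length(conditions) >= 1, n_nuclei >= 1,
            !is.null(names(conditions)))
  if (dir.exists(dir) && !overwrite)
    stop("output directory exists (use overwrite = TRUE): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, pitch_nm = pitch_nm, conditions = list())
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    cfg <- conditions[[ci]]
    stopifnot(inherits(cfg, "sim_config"))
    nuclei <- list()
    for (ni in seq_len(n_nuclei)) {
      s <- derive_seed(seed, ci, ni)
      nuc <- generate_nucleus(cfg, seed = s)
      base <- file.path(dir, sprintf("%s_nucleus%03d", cname, ni))
      files <- list()
      for (chn in names(nuc$tables)) {
        f <- paste0(base, "_", chn, ".csv")
        write_localizations(nuc$tables[[chn]], f)
        files[[chn]] <- basename(f)
      }
      bounds <- polygon_bounds(nuc$roi_polygon, pitch_nm)
      roi <- load_roi(polygon = nuc$roi_polygon, pitch_nm = pitch_nm,
                      bounds = bounds)
      roi_file <- paste0(base, "_roi.png")
      write_roi_mask(roi, roi_file)
      truth_file <- paste0(base, "_truth.csv")
      write.csv(nuc$truth, truth_file, row.names = FALSE)
      nuclei[[ni]] <- list(
        id = sprintf("%s_nucleus%03d", cname, ni), seed = s,
        channels = files, roi = basename(roi_file),
        roi_bounds_nm = bounds, truth = basename(truth_file))
    }
    manifest$conditions[[cname]] <- list(
      config = unclass(cfg), n_nuclei = n_nuclei, nuclei = nuclei)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
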