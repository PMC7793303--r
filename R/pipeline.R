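#' Welch two-sample t-test summary for per-nucleus factors
#'
#' Two-sided Welch (unequal-variance) test, the default comparison between
#' a treated condition and control; groups are summarized as mean with
#' standard error of the mean.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @return list with \code{t}, \code{p}, \code{df}, per-group mean and
#'   s.e.m., and a significance label (ns, *, **, ***, ****).
#' @export
ttest_summary <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need >= 2 values per group")
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_A = mean(groupA), sem_A = sem(groupA),
       mean_B = mean(groupB), sem_B = sem(groupB),
       significance = significance_label(tt$p.value))
}

# figure-legend style significance bands; rendering annotation only --
# no multiple-testing correction is applied anywhere in the pipeline
significance_label <- function(p) {
  if (is.na(p)) ""
  else if (p > 0.05) "ns"
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else if (p > 0.0001) "***"
  else "****"
}

#' Segment all channels of one nucleus
#'
#' Renders each localization table over shared bounds derived from the ROI
#' polygon and segments it inside the ROI; the common entry point used by
#' \code{\link{run_study}} and by end-to-end analyses of a single nucleus.
#'
#' @param tables named list of \code{\link{localization_table}}s.
#' @param roi_polygon two-column matrix of ROI vertices (nm).
#' @param pitch_nm rendering pitch (default 20).
#' @param min_area_px minimum cluster area (default 2).
#' @return list with \code{clusters} (named list of \code{cluster_set}s),
#'   \code{roi}, \code{images}.
#' @export
analyze_nucleus <- function(tables, roi_polygon, pitch_nm = 20,
                            min_area_px = 2) {
  bounds <- polygon_bounds(roi_polygon, pitch_nm)
  roi <- load_roi(polygon = roi_polygon, pitch_nm = pitch_nm,
                  bounds = bounds)
  images <- lapply(tables, render, pitch_nm = pitch_nm, bounds = bounds)
  clusters <- lapply(images, segment_clusters, roi = roi,
                     min_area_px = min_area_px)
  list(clusters = clusters, roi = roi, images = images)
}

#' Run a complete multi-condition study
#'
#' End-to-end orchestration over synthetic conditions: for each nucleus,
#' generate (or load) localization tables, render and segment the channels,
#' and compute the three analysis tiers: (1) Monte Carlo-normalized
#' colocalization factors per nucleus, summarized per condition and
#' compared to control by Welch t-test; (2) three-color co-occupancy
#' fractions at reference foci; (3) pooled intrafocus center-of-mass
#' distance distribution with Gaussian fitting and proximal/distal
#' classification. Identical (conditions, seed) input yields identical
#' output. A nucleus failing a stage is excluded with a recorded reason;
#' more than 50\% failures abort the run.
#'
#' @param conditions named list of \code{\link{sim_config}} objects, or a
#'   path to a dataset directory written by \code{\link{generate_study}}.
#' @param n_nuclei nuclei per condition (ignored when loading from disk).
#' @param control name of the control condition (default the first).
#' @param pair length-2 channel names for tier 1, static channel first
#'   (default \code{c("nadna", "A")}).
#' @param metric \code{"count"} or \code{"area"} for tier 1.
#' @param n_sims Monte Carlo redistributions per nucleus (default 20).
#' @param pitch_nm rendering pitch (default 20).
#' @param min_area_px minimum cluster area (default 2).
#' @param seed run seed; per-nucleus seeds are derived from it.
#' @param three_color also run tiers 2 and 3 on channels A and B
#'   (default TRUE).
#' @param out_dir optional directory for CSV/JSON reports.
#' @return list of class \code{study_result}: \code{per_nucleus}
#'   data.frame, \code{summaries} (per non-control condition),
#'   \code{cooccupancy} and \code{intrafoci} per condition (if requested),
#'   \code{failures}, \code{seed}.
#' @export
run_study <- function(conditions, n_nuclei = 10, control = NULL,
                      pair = c("nadna", "A"), metric = c("count", "area"),
                      n_sims = 20, pitch_nm = 20, min_area_px = 2,
                      seed = 1, three_color = TRUE, out_dir = NULL) {
  metric <- match.arg(metric)
  from_disk <- is.character(conditions) && length(conditions) == 1
  if (from_disk) {
    manifest <- jsonlite::read_json(file.path(conditions, "manifest.json"),
                                    simplifyVector = FALSE)
    cond_names <- names(manifest$conditions)
    data_dir <- conditions
  } else {
    stopifnot(is.list(conditions), !is.null(names(conditions)))
    cond_names <- names(conditions)
  }
  control <- control %||% cond_names[1]
  if (!control %in% cond_names) stop("unknown control condition: ", control)

  rows <- list(); failures <- list()
  distances <- list(); classifications <- list()
  for (ci in seq_along(cond_names)) {
    cname <- cond_names[ci]
    nn <- if (from_disk) length(manifest$conditions[[cname]]$nuclei)
          else n_nuclei
    for (ni in seq_len(nn)) {
      nuc_id <- sprintf("%s_nucleus%03d", cname, ni)
      res <- tryCatch({
        if (from_disk) {
          rec <- manifest$conditions[[cname]]$nuclei[[ni]]
          tables <- lapply(rec$channels, function(f)
            read_localizations(file.path(data_dir, f)))
          bounds <- unlist(rec$roi_bounds_nm)
          roi <- load_roi(path = file.path(data_dir, rec$roi),
                          pitch_nm = pitch_nm, bounds = bounds)
          images <- lapply(tables, render, pitch_nm = pitch_nm,
                           bounds = bounds)
          clusters <- lapply(images, segment_clusters, roi = roi,
                             min_area_px = min_area_px)
          an <- list(clusters = clusters, roi = roi)
        } else {
          nuc <- generate_nucleus(conditions[[cname]],
                                  seed = derive_seed(seed, ci, ni))
          an <- analyze_nucleus(nuc$tables, nuc$roi_polygon,
                                pitch_nm = pitch_nm,
                                min_area_px = min_area_px)
        }
        cf <- coloc_factor(an$clusters[[pair[1]]], an$clusters[[pair[2]]],
                           an$roi, metric = metric, n_sims = n_sims,
                           seed = derive_seed(seed, ci, ni) + 1L)
        row <- data.frame(condition = cname, nucleus = nuc_id,
                          real = cf$real, null_mean = mean(cf$null),
                          factor = cf$factor)
        tier23 <- NULL
        if (three_color &&
            all(c("nadna", "A", "B") %in% names(an$clusters))) {
          cls <- classify_foci(an$clusters$nadna, an$clusters$A,
                               an$clusters$B, nucleus = nuc_id)
          dd <- pair_distances(an$clusters$A, an$clusters$B,
                               nadna = an$clusters$nadna, nucleus = nuc_id)
          tier23 <- list(cls = cls, dd = dd)
        }
        list(row = row, tier23 = tier23)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[nuc_id]] <- conditionMessage(res)
      } else {
        rows[[nuc_id]] <- res$row
        if (!is.null(res$tier23)) {
          classifications[[cname]] <-
            rbind(classifications[[cname]], res$tier23$cls)
          distances[[cname]] <- rbind(distances[[cname]], res$tier23$dd)
        }
      }
    }
  }
  n_attempted <- length(rows) + length(failures)
  if (length(failures) > 0.5 * n_attempted)
    stop("more than half of the nuclei failed; first failure: ",
         failures[[1]])
  per_nucleus <- do.call(rbind, rows)
  rownames(per_nucleus) <- NULL

  summaries <- list()
  ctrl_f <- per_nucleus$factor[per_nucleus$condition == control]
  for (cname in setdiff(cond_names, control)) {
    f <- per_nucleus$factor[per_nucleus$condition == cname]
    if (length(f) >= 2 && length(ctrl_f) >= 2)
      summaries[[cname]] <- summarize_condition(
        f, ctrl_f, label = cname, control_label = control)
  }

  coocc <- list(); intrafoci <- list()
  if (three_color) {
    for (cname in names(classifications)) {
      cls <- classifications[[cname]]
      if (!is.null(cls) && nrow(cls) > 0)
        coocc[[cname]] <- cooccupancy_fractions(cls, grouping = "pooled")
      dd <- distances[[cname]]
      if (!is.null(dd) && nrow(dd) >= 20) {
        fit <- tryCatch(fit_association(dd), error = function(e) NULL)
        if (!is.null(fit))
          intrafoci[[cname]] <- list(
            fit = fit, class = classify_association(fit))
      }
    }
  }

  out <- structure(list(
    per_nucleus = per_nucleus, summaries = summaries,
    cooccupancy = coocc, intrafoci = intrafoci,
    failures = failures, control = control, pair = pair,
    metric = metric, n_sims = n_sims, seed = seed
  ), class = "study_result")
  if (!is.null(out_dir)) write_study_report(out, out_dir)
  out
}

write_study_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$per_nucleus, file.path(dir, "per_nucleus.csv"),
            row.names = FALSE)
  summ <- lapply(result$summaries, function(s)
    s[c("label", "n", "mean", "sem", "control_mean", "control_sem",
        "delta", "delta_sem", "t", "p")])
  report <- list(
    control = result$control, pair = result$pair, metric = result$metric,
    n_sims = result$n_sims, seed = result$seed,
    summaries = summ,
    cooccupancy = lapply(result$cooccupancy, function(x)
      x[c("f_A_only", "f_B_only", "f_both", "n_foci")]),
    intrafoci = lapply(result$intrafoci, function(x) list(
      model = x$fit$model, label = x$class$label,
      components = x$fit$components)),
    failures = result$failures
  )
  jsonlite::write_json(report, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", nrow(x$per_nucleus), "nuclei,",
      length(x$failures), "failures; pair",
      paste(x$pair, collapse = "/"), "metric", x$metric, "\n")
  for (s in x$summaries) print(s)
  invisible(x)
}
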