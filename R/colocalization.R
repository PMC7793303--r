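#' Randomly redistribute clusters within the nuclear ROI
#'
#' Each cluster is rigidly translated (shape preserved, no rotation) to an
#' independent uniform position with all of its pixels inside the ROI;
#' redistributed clusters may overlap one another. This is the Monte Carlo
#' null used to normalize colocalization: the real image of one channel is
#' held static while the other channel's clusters are redrawn at random.
#'
#' @param clusters a \code{cluster_set} (typically channel 2).
#' @param roi a \code{nucleus_roi} on the same grid.
#' @param max_attempts rejection-sampling cap per cluster (default 10000).
#' @return a \code{cluster_set} with translated pixel sets; areas and
#'   per-pixel counts are unchanged, centers of mass are shifted.
#' @export
randomize_clusters <- function(clusters, roi, max_attempts = 10000) {
  nr <- clusters$dim[1]; nc <- clusters$dim[2]
  stopifnot(all(dim(roi) == clusters$dim))
  mask <- as.vector(roi)
  out <- clusters
  for (ci in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[ci]]
    ri <- cl$row - min(cl$row)          # shape relative to its bbox corner
    rj <- cl$col - min(cl$col)
    h <- max(ri); w <- max(rj)
    if (h + 1 > nr || w + 1 > nc)
      stop("cluster ", cl$id, " larger than the image")
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      i0 <- sample.int(nr - h, 1)
      j0 <- sample.int(nc - w, 1)
      px <- (j0 + rj - 1L) * nr + (i0 + ri)
      if (all(mask[px])) {
        di <- (i0 - min(cl$row)); dj <- (j0 - min(cl$col))
        cl$row <- i0 + ri; cl$col <- j0 + rj; cl$px <- px
        cl$com_nm <- cl$com_nm + c(dj, di) * clusters$pitch_nm
        out$clusters[[ci]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cluster ", cl$id, " inside the ROI within ",
           max_attempts, " attempts")
  }
  out
}

# overlap between two cluster sets on one grid
overlap_measure <- function(ch1, ch2, metric = c("count", "area"),
                            pair_counting = FALSE) {
  metric <- match.arg(metric)
  m2 <- cluster_union_mask(ch2)
  if (metric == "count") {
    if (!pair_counting) {
      # focus-centric: number of channel-1 foci sharing >= 1 pixel with
      # any channel-2 cluster
      sum(vapply(ch1$clusters, function(cl) any(m2[cl$px]), logical(1)))
    } else {
      sum(vapply(ch1$clusters, function(cl) {
        sum(vapply(ch2$clusters, function(c2)
          any(c2$px %in% cl$px), logical(1)))
      }, numeric(1)))
    }
  } else {
    m1 <- cluster_union_mask(ch1)
    sum(m1 & m2) * ch1$pitch_nm^2       # shared area in nm^2
  }
}

#' Monte Carlo-normalized colocalization factor for one nucleus
#'
#' Computes the observed two-channel overlap and divides it by the mean
#' overlap across \code{n_sims} random redistributions of the channel-2
#' clusters within the ROI. A factor of 1 means the observed associations
#' are indistinguishable from random placement; 2 means twice as many as
#' random, 3 triple, and so on. The normalization absorbs nucleus-to-
#' nucleus differences in size and in the number, size and density of
#' clusters.
#'
#' @param ch1 static-channel \code{cluster_set} (e.g. naDNA foci).
#' @param ch2 \code{cluster_set} whose clusters are randomized.
#' @param roi a \code{nucleus_roi} on the same grid.
#' @param metric \code{"count"} (number of channel-1 foci overlapping at
#'   least one channel-2 cluster; appropriate for sparse markers) or
#'   \code{"area"} (total shared area in nm^2; appropriate for markers
#'   that accumulate).
#' @param n_sims number of random redistributions (default 20).
#' @param pair_counting count overlapping (focus, cluster) pairs instead
#'   of positive foci (default FALSE).
#' @param seed optional RNG seed for the randomizations.
#' @return object of class \code{coloc_result}: \code{real}, \code{null}
#'   (the \code{n_sims} simulated overlaps), \code{factor}
#'   (\code{real / mean(null)}; \code{NaN} with a warning if the null mean
#'   is zero), \code{metric}, \code{n_sims}.
#' @export
coloc_factor <- function(ch1, ch2, roi, metric = c("count", "area"),
                         n_sims = 20, pair_counting = FALSE, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_sims >= 1)
  if (length(ch1$clusters) == 0 || length(ch2$clusters) == 0)
    stop("need >= 1 cluster in each channel")
  if (!is.null(seed)) set.seed(seed)
  real <- overlap_measure(ch1, ch2, metric, pair_counting)
  null <- vapply(seq_len(n_sims), function(s) {
    overlap_measure(ch1, randomize_clusters(ch2, roi), metric, pair_counting)
  }, numeric(1))
  fac <- if (mean(null) > 0) real / mean(null) else {
    warning("null overlap mean is zero; factor undefined (NaN)")
    NaN
  }
  structure(list(real = real, null = null, factor = fac,
                 metric = metric, n_sims = n_sims),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result (%s): real %.4g, null mean %.4g, factor %.3f\n",
              x$metric, x$real, mean(x$null), x$factor))
  invisible(x)
}

#' Engineer channel-2 clusters realizing a chosen overlap count
#'
#' Used to plant a known enrichment: channel-2 clusters are re-placed
#' uniformly at random inside the ROI (the same placement law as the Monte
#' Carlo null) under an acceptance rule that drives the realized
#' focus-centric overlap count to exactly \code{n_overlap}: a placement is
#' kept while it touches only previously untouched channel-1 clusters
#' without overshooting the target, and once the target is reached all
#' remaining clusters are placed with zero channel-1 contact.
#'
#' @param ch1 static-channel \code{cluster_set}.
#' @param ch2 \code{cluster_set} providing the shapes to re-place.
#' @param roi a \code{nucleus_roi}.
#' @param n_overlap desired overlap count (<= number of channel-1 clusters
#'   and achievable with the available channel-2 clusters).
#' @param max_attempts rejection cap per cluster.
#' @return a \code{cluster_set} whose realized overlap count (metric
#'   \code{"count"}) equals \code{n_overlap}.
#' @export
plant_overlaps <- function(ch1, ch2, roi, n_overlap, max_attempts = 10000) {
  n1 <- length(ch1$clusters); n2 <- length(ch2$clusters)
  if (n_overlap > n1)
    stop("n_overlap (", n_overlap, ") exceeds channel-1 clusters (", n1, ")")
  nr <- ch2$dim[1]; nc <- ch2$dim[2]
  stopifnot(all(dim(roi) == ch2$dim), all(ch1$dim == ch2$dim))
  mask <- as.vector(roi)
  # per-pixel channel-1 cluster index (clusters are pixel-disjoint)
  idmap <- integer(nr * nc)
  for (k in seq_len(n1)) idmap[ch1$clusters[[k]]$px] <- k
  touched <- logical(n1)
  remaining <- n_overlap
  out <- ch2
  commit <- function(cl, i0, j0, px, ri, rj) {
    cl$row <- i0 + ri; cl$col <- j0 + rj
    cl$px <- px
    ctr <- pixel_centers(cl$row, cl$col, ch2$pitch_nm, ch2$origin_nm)
    w <- cl$counts
    cl$com_nm <- c(x = sum(w * ctr[, 1]) / sum(w),
                   y = sum(w * ctr[, 2]) / sum(w))
    cl
  }
  order2 <- sample.int(n2)   # visit shapes in random order
  for (k in order2) {
    cl <- ch2$clusters[[k]]
    ri <- cl$row - min(cl$row); rj <- cl$col - min(cl$col)
    h <- max(ri); w <- max(rj)
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      i0 <- sample.int(nr - h, 1); j0 <- sample.int(nc - w, 1)
      px <- (j0 + rj - 1L) * nr + (i0 + ri)
      if (!all(mask[px])) next
      hit <- unique(idmap[px]); hit <- hit[hit > 0L]
      new_hits <- hit[!touched[hit]]
      ok <- if (remaining > 0)
        length(hit) == length(new_hits) && length(new_hits) >= 1 &&
          length(new_hits) <= remaining
      else length(hit) == 0
      if (ok) {
        touched[new_hits] <- TRUE
        remaining <- remaining - length(new_hits)
        out$clusters[[k]] <- commit(cl, i0, j0, px, ri, rj)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cluster ", cl$id, " within ", max_attempts,
           " attempts (", remaining, " planted overlaps still needed)")
  }
  if (remaining > 0)
    stop("ran out of channel-2 clusters with ", remaining,
         " planted overlaps still needed")
  out
}

#' Summarize per-nucleus colocalization factors for a condition
#'
#' Aggregates per-nucleus factors into a condition mean with its standard
#' error and compares against the control condition: the change is the
#' difference of means (so a decrease in protein association appears as a
#' negative change), with a two-sided Welch two-sample t-test.
#'
#' @param results numeric vector of per-nucleus factors, or a list of
#'   \code{coloc_result} objects.
#' @param control same, for the control condition.
#' @param label,control_label condition names for printing.
#' @return object of class \code{condition_summary}: per-condition mean,
#'   s.e.m. and n; \code{delta} (treated mean minus control mean) with
#'   propagated s.e.m.; Welch \code{t} and \code{p}.
#' @export
summarize_condition <- function(results, control, label = "treated",
                                control_label = "control") {
  as_factors <- function(r) {
    if (is.numeric(r)) r
    else vapply(r, function(x) x$factor, numeric(1))
  }
  f <- as_factors(results); f0 <- as_factors(control)
  f <- f[is.finite(f)]; f0 <- f0[is.finite(f0)]
  if (length(f0) == 0) stop("empty control condition")
  if (length(f) < 2 || length(f0) < 2)
    stop("need >= 2 nuclei per condition for s.e.m.")
  # degenerate (zero-variance) inputs leave the test undefined, not an error
  tt <- tryCatch(t.test(f, f0, var.equal = FALSE),
                 error = function(e)
                   list(statistic = NA_real_, p.value = NA_real_))
  structure(list(
    label = label, control_label = control_label,
    n = length(f), mean = mean(f), sem = sem(f),
    control_n = length(f0), control_mean = mean(f0), control_sem = sem(f0),
    delta = mean(f) - mean(f0),
    delta_sem = sqrt(sem(f)^2 + sem(f0)^2),
    t = unname(tt$statistic), p = tt$p.value
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "%s: %.3f +/- %.3f (n=%d) vs %s: %.3f +/- %.3f (n=%d)\n  delta %.3f +/- %.3f, Welch t=%.3f, p=%.3g %s\n",
    x$label, x$mean, x$sem, x$n, x$control_label, x$control_mean,
    x$control_sem, x$control_n, x$delta, x$delta_sem, x$t, x$p,
    significance_label(x$p)))
  invisible(x)
}
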