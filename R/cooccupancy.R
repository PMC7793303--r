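#' Classify reference foci by marker co-occupancy
#'
#' For each reference-channel (naDNA) focus, tests overlap (>= 1 shared
#' pixel, the same rule used by the colocalization module) with the
#' clusters of two marker channels. Foci overlapping neither marker are
#' excluded from the returned classification and counted separately as
#' unaffected; this is how analysis focuses on the subset of replication
#' foci engaged by at least one response protein.
#'
#' @param nadna reference-channel \code{cluster_set}.
#' @param chA,chB marker-channel \code{cluster_set}s on the same grid.
#' @param nucleus optional nucleus id recorded per row.
#' @return data.frame of class \code{focus_classification} with columns
#'   \code{focus_id}, \code{has_A}, \code{has_B} (one row per focus
#'   positive for at least one marker), plus attributes
#'   \code{n_unaffected} and \code{n_total}.
#' @export
classify_foci <- function(nadna, chA, chB, nucleus = NA) {
  if (!all(nadna$dim == chA$dim) || !all(nadna$dim == chB$dim))
    stop("cluster sets are on different grids")
  mA <- cluster_union_mask(chA)
  mB <- cluster_union_mask(chB)
  has_A <- vapply(nadna$clusters, function(cl) any(mA[cl$px]), logical(1))
  has_B <- vapply(nadna$clusters, function(cl) any(mB[cl$px]), logical(1))
  keep <- has_A | has_B
  out <- data.frame(
    nucleus = rep(nucleus, sum(keep)),
    focus_id = vapply(nadna$clusters, `[[`, 1L, "id")[keep],
    has_A = has_A[keep], has_B = has_B[keep]
  )
  attr(out, "n_unaffected") <- sum(!keep)
  attr(out, "n_total") <- length(keep)
  class(out) <- c("focus_classification", "data.frame")
  out
}

#' Co-occupancy fractions among marker-positive foci
#'
#' Among foci positive for at least one of the two markers, the fractions
#' positive for A only, B only, or both. Pooled mode computes fractions
#' over all foci (summing to 1 exactly); per-nucleus mode averages the
#' per-nucleus fractions and reports the s.e.m. across nuclei.
#'
#' @param classifications a \code{focus_classification} data.frame (rows
#'   from several nuclei may be concatenated; per-nucleus mode requires
#'   the \code{nucleus} column to be filled).
#' @param grouping \code{"pooled"} or \code{"nucleus"}.
#' @return list of class \code{cooccupancy_fractions}: \code{f_A_only},
#'   \code{f_B_only}, \code{f_both}, \code{n_foci}; in per-nucleus mode
#'   also \code{sem} (named vector) and \code{n_nuclei}.
#' @export
cooccupancy_fractions <- function(classifications,
                                  grouping = c("pooled", "nucleus")) {
  grouping <- match.arg(grouping)
  cls <- classifications
  if (nrow(cls) == 0) stop("no classified foci: fractions undefined")
  frac1 <- function(d) {
    n <- nrow(d)
    c(A_only = sum(d$has_A & !d$has_B) / n,
      B_only = sum(!d$has_A & d$has_B) / n,
      both = sum(d$has_A & d$has_B) / n)
  }
  if (grouping == "pooled") {
    f <- frac1(cls)
    out <- list(f_A_only = f[["A_only"]], f_B_only = f[["B_only"]],
                f_both = f[["both"]], n_foci = nrow(cls),
                grouping = "pooled")
  } else {
    if (any(is.na(cls$nucleus)))
      stop("per-nucleus grouping requires the nucleus column")
    per <- t(vapply(split(cls, cls$nucleus), frac1, numeric(3)))
    out <- list(f_A_only = mean(per[, "A_only"]),
                f_B_only = mean(per[, "B_only"]),
                f_both = mean(per[, "both"]),
                sem = apply(per, 2, sem),
                n_foci = nrow(cls), n_nuclei = nrow(per),
                grouping = "nucleus")
  }
  class(out) <- "cooccupancy_fractions"
  out
}

#' @export
print.cooccupancy_fractions <- function(x, ...) {
  cat(sprintf(
    "co-occupancy (%s, %d foci): A only %.1f%%, B only %.1f%%, both %.1f%%\n",
    x$grouping, x$n_foci, 100 * x$f_A_only, 100 * x$f_B_only,
    100 * x$f_both))
  invisible(x)
}
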