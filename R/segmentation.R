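#' Otsu threshold restricted to the nuclear ROI
#'
#' Computes the threshold maximizing the between-class variance of the
#' integer pixel counts that lie inside the ROI; pixels outside the ROI
#' never influence the threshold. Foreground is defined as strictly greater
#' than the returned threshold.
#'
#' @param image a \code{rendered_image} (integer counts).
#' @param roi a \code{nucleus_roi} of the same shape.
#' @return the threshold value (a pixel count).
#' @export
otsu_in_roi <- function(image, roi) {
  if (!all(dim(image) == dim(roi))) stop("image and ROI shapes differ")
  v <- as.vector(image)[as.vector(roi)]
  if (length(v) == 0) stop("empty ROI")
  if (min(v) == max(v)) stop("constant image inside ROI: no threshold exists")
  vmax <- max(v)
  h <- tabulate(v + 1L, nbins = vmax + 1L)  # counts of values 0..vmax
  vals <- 0:vmax
  p <- h / sum(h)
  w0 <- cumsum(p)
  m0 <- cumsum(p * vals)
  mt <- m0[length(m0)]
  # candidate thresholds t = vals[k]: class0 = {<= t}, class1 = {> t}
  k <- seq_len(vmax)  # exclude the top value (class1 would be empty)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sb <- rep(-Inf, vmax)
  sb[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  vals[which.max(sb)]  # ties -> lowest threshold (deterministic)
}

#' Segment foci inside the ROI into connected clusters
#'
#' Thresholds the image (Otsu inside the ROI unless a threshold is given),
#' intersects the foreground with the ROI, labels 8-connected components,
#' and drops components smaller than \code{min_area_px}. Each cluster's
#' center of mass is the localization-count-weighted centroid of its pixels
#' (binary centroid available via \code{weighted = FALSE}).
#'
#' @param image a \code{rendered_image}.
#' @param roi a \code{nucleus_roi} of the same shape.
#' @param min_area_px minimum cluster area in pixels (default 2).
#' @param threshold optional fixed threshold; default: Otsu inside the ROI.
#'   If Otsu is degenerate (constant image) an empty cluster set is
#'   returned when the image is all-zero, otherwise the error propagates.
#' @param weighted weight the centroid by per-pixel counts (default TRUE).
#' @return an object of class \code{cluster_set}: a list with one entry per
#'   cluster (pixel indices, per-pixel counts, area, localization count,
#'   center of mass in nm) plus grid metadata. \code{as.data.frame} gives a
#'   per-cluster summary table.
#' @export
segment_clusters <- function(image, roi, min_area_px = 2, threshold = NULL,
                             weighted = TRUE) {
  if (!all(dim(image) == dim(roi))) stop("image and ROI shapes differ")
  g <- grid_info(image)
  empty <- function() {
    structure(list(clusters = list(), channel = attr(image, "channel"),
                   pitch_nm = g$pitch_nm, origin_nm = g$origin_nm,
                   dim = dim(image), threshold = threshold),
              class = "cluster_set")
  }
  v <- as.vector(image)[as.vector(roi)]
  if (length(v) > 0 && min(v) == max(v) && is.null(threshold)) {
    if (max(v) == 0) return(empty())  # blank channel: no foci
    stop("constant nonzero image inside ROI: supply a threshold")
  }
  if (is.null(threshold)) threshold <- otsu_in_roi(image, roi)
  fg <- (image > threshold) & roi
  labels <- label_components(fg)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  nr <- nrow(image)
  clusters <- list()
  for (id in ids) {
    px <- which(labels == id)
    if (length(px) < min_area_px) next
    i <- ((px - 1L) %% nr) + 1L
    j <- ((px - 1L) %/% nr) + 1L
    cnt <- as.numeric(image[px])
    w <- if (weighted) cnt else rep(1, length(px))
    ctr <- pixel_centers(i, j, g$pitch_nm, g$origin_nm)
    clusters[[length(clusters) + 1L]] <- list(
      id = length(clusters) + 1L,
      px = px, row = i, col = j, counts = cnt,
      area_px = length(px),
      n_locs = sum(cnt),
      com_nm = c(x = sum(w * ctr[, 1]) / sum(w),
                 y = sum(w * ctr[, 2]) / sum(w))
    )
  }
  out <- empty()
  out$clusters <- clusters
  out$threshold <- threshold
  out
}

# 8-connected component labeling via graph components over foreground pixels
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)  # foreground pixel -> vertex id
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    i2 <- i + d[1]; j2 <- j + d[2]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    nb <- (j2[ok] - 1L) * nr + i2[ok]
    hit <- fg[nb]
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(pos[idx[ok]][hit], pos[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (length(x$clusters) == 0)
    return(data.frame(id = integer(0), area_px = integer(0),
                      n_locs = numeric(0), com_x_nm = numeric(0),
                      com_y_nm = numeric(0)))
  data.frame(
    id = vapply(x$clusters, `[[`, 1L, "id"),
    area_px = vapply(x$clusters, `[[`, 1L, "area_px"),
    n_locs = vapply(x$clusters, `[[`, 1, "n_locs"),
    com_x_nm = vapply(x$clusters, function(cl) cl$com_nm[["x"]], 1),
    com_y_nm = vapply(x$clusters, function(cl) cl$com_nm[["y"]], 1)
  )
}

#' @export
length.cluster_set <- function(x) length(x$clusters)

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      "pitch", x$pitch_nm, "nm, threshold", x$threshold, "\n")
  invisible(x)
}

#' Shared pixel count between two clusters
#'
#' @param a,b single clusters (elements of a \code{cluster_set}) from
#'   images on the same grid.
#' @param pitch_nm pixel pitch, used to also report the overlap area in nm^2.
#' @return list with \code{px} (shared pixel count) and \code{area_nm2}.
#' @export
cluster_overlap <- function(a, b, pitch_nm = 20) {
  n <- length(intersect(a$px, b$px))
  list(px = n, area_nm2 = n * pitch_nm^2)
}

# union of all cluster pixels as a logical vector over the image grid
cluster_union_mask <- function(cs) {
  m <- logical(prod(cs$dim))
  for (cl in cs$clusters) m[cl$px] <- TRUE
  m
}
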