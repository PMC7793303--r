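# in-code fixtures shared across test files

# localization table from bare coordinates
loc_tab <- function(x, y, channel = "test") {
  localization_table(x, y, channel = channel)
}

# rectangular ROI polygon covering [0, w] x [0, h] nm
rect_poly <- function(w, h, x0 = 0, y0 = 0) {
  cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

rect_roi <- function(w_nm, h_nm, pitch = 20) {
  load_roi(polygon = rect_poly(w_nm, h_nm), pitch_nm = pitch,
           bounds = c(0, w_nm, 0, h_nm))
}

# build a cluster_set directly from pixel index lists (1-based (row, col)),
# bypassing segmentation, for toy geometry tests
toy_cluster_set <- function(pixlists, dim, pitch = 20, origin = c(0, 0),
                            counts = NULL, channel = "toy") {
  nr <- dim[1]
  clusters <- lapply(seq_along(pixlists), function(k) {
    rc <- pixlists[[k]]
    i <- rc[, 1]; j <- rc[, 2]
    px <- (j - 1L) * nr + i
    cnt <- if (is.null(counts)) rep(1, length(px)) else counts[[k]]
    ctr <- cbind(origin[1] + (j - 0.5) * pitch, origin[2] + (i - 0.5) * pitch)
    list(id = k, px = px, row = i, col = j, counts = cnt,
         area_px = length(px), n_locs = sum(cnt),
         com_nm = c(x = sum(cnt * ctr[, 1]) / sum(cnt),
                    y = sum(cnt * ctr[, 2]) / sum(cnt)))
  })
  structure(list(clusters = clusters, channel = channel, pitch_nm = pitch,
                 origin_nm = origin, dim = dim, threshold = 0),
            class = "cluster_set")
}

# square block of pixels centered at (i, j)
block_px <- function(i, j, half = 1) {
  as.matrix(expand.grid(i = (i - half):(i + half), j = (j - half):(j + half)))
}

# independent exhaustive Otsu oracle: try every candidate threshold and
# compute the between-class variance directly from class moments
otsu_oracle <- function(values) {
  cand <- sort(unique(values))
  cand <- cand[-length(cand)]
  best_t <- NA
  best_v <- -Inf
  for (t in cand) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# brute-force mutual nearest neighbor pairing oracle (O(n^2) loops)
mutual_nn_oracle <- function(ref, other, radius_nm) {
  n <- nrow(ref); m <- nrow(other)
  pairs <- list()
  for (i in seq_len(n)) {
    d_i <- sqrt((other$x_nm - ref$x_nm[i])^2 + (other$y_nm - ref$y_nm[i])^2)
    j <- which.min(d_i)
    d_j <- sqrt((ref$x_nm - other$x_nm[j])^2 + (ref$y_nm - other$y_nm[j])^2)
    if (which.min(d_j) == i && d_i[j] <= radius_nm)
      pairs[[length(pairs) + 1]] <- c(i = i, j = j)
  }
  do.call(rbind, pairs)
}
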