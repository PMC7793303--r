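# internal helpers shared across modules

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

fwhm_to_sigma <- function(fwhm) fwhm * FWHM_TO_SIGMA
sigma_to_fwhm <- function(sigma) sigma / FWHM_TO_SIGMA

# radial offset: distance drawn from a Gaussian truncated at 0, angle uniform
rtrunc_radial <- function(n, center_nm, fwhm_nm) {
  sigma <- fwhm_to_sigma(fwhm_nm)
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(n, center_nm, sigma)
    out <- c(out, d[d >= 0])
  }
  out[seq_len(n)]
}

# uniform points inside an ellipse with semi-axes (a, b) nm centered at c0
runif_in_ellipse <- function(n, a_nm, b_nm, center_nm = c(0, 0)) {
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center_nm[1] + a_nm * r * cos(th),
        y = center_nm[2] + b_nm * r * sin(th))
}

# uniform points inside an arbitrary polygon (bbox rejection)
runif_in_polygon <- function(n, poly) {
  xs <- range(poly[, 1]); ys <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    x <- runif(m, xs[1], xs[2]); y <- runif(m, ys[1], ys[2])
    keep <- pracma::inpolygon(x, y, poly[, 1], poly[, 2])
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

ellipse_polygon <- function(a_nm, b_nm, center_nm = c(0, 0), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center_nm[1] + a_nm * cos(th), y = center_nm[2] + b_nm * sin(th))
}

sem <- function(x) sd(x) / sqrt(length(x))

# deterministic per-nucleus seed derived from the run seed; kept < 2^31
derive_seed <- function(seed, condition_idx, nucleus_idx) {
  (abs(seed) %% 100000L) * 16384L + condition_idx * 512L + nucleus_idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
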