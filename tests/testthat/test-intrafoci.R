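test_that("pair distances reproduce toy geometry", {
  dimg <- c(100, 100)
  # one focus hosting A at its CoM and B 135 nm away along y
  foci <- toy_cluster_set(list(block_px(20, 20, 5)), dim = dimg)
  chA <- toy_cluster_set(list(cbind(18, 20)), dim = dimg)
  # B's count-weighted CoM sits exactly 135 nm from A along y: pixel
  # centers are 20 nm apart, so weight two stacked pixels 0.25/0.75
  chB <- toy_cluster_set(list(rbind(c(24, 20), c(25, 20))), dim = dimg,
                         counts = list(c(0.25, 0.75)))
  dA <- chA$clusters[[1]]$com_nm
  dB <- chB$clusters[[1]]$com_nm
  expect_equal(sqrt(sum((dA - dB)^2)), 135)
  dd <- pair_distances(chA, chB, nadna = foci)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$d_nm, 135)
  # focus with A only -> no sample
  dd0 <- pair_distances(chA, toy_cluster_set(list(cbind(90, 90)),
                                             dim = dimg), nadna = foci)
  expect_equal(nrow(dd0), 0)
})

test_that("per-focus nearest pair equals the brute-force oracle", {
  set.seed(81)
  cfg <- sim_config(n_foci = 50, cooccupancy = c(A = 0, B = 0, AB = 0.8))
  nuc <- generate_nucleus(cfg, seed = 81)
  an <- analyze_nucleus(nuc$tables, nuc$roi_polygon)
  dd <- pair_distances(an$clusters$A, an$clusters$B,
                       nadna = an$clusters$nadna)
  # oracle: explicit loops over focus pixels and all A-B pairs
  oracle <- c()
  comA <- t(sapply(an$clusters$A$clusters, `[[`, "com_nm"))
  comB <- t(sapply(an$clusters$B$clusters, `[[`, "com_nm"))
  for (cl in an$clusters$nadna$clusters) {
    ia <- c(); ib <- c()
    for (k in seq_along(an$clusters$A$clusters))
      if (length(intersect(an$clusters$A$clusters[[k]]$px, cl$px)) > 0)
        ia <- c(ia, k)
    for (k in seq_along(an$clusters$B$clusters))
      if (length(intersect(an$clusters$B$clusters[[k]]$px, cl$px)) > 0)
        ib <- c(ib, k)
    if (length(ia) && length(ib)) {
      best <- Inf
      for (i in ia) for (j in ib)
        best <- min(best, sqrt(sum((comA[i, ] - comB[j, ])^2)))
      oracle <- c(oracle, best)
    }
  }
  expect_equal(sort(dd$d_nm), sort(oracle))
})

test_that("single-Gaussian fits recover planted distance populations", {
  set.seed(82)
  d_prox <- rnorm(200, 135, 31.9)
  fit <- fit_association(d_prox)
  expect_equal(fit$model, "single")
  expect_lt(abs(fit$components$center_nm - 135), 8)
  expect_equal(classify_association(fit)$label, "intimate")
  d_dist <- rnorm(200, 250, 40)
  fit2 <- fit_association(d_dist)
  expect_equal(fit2$model, "single")
  expect_lt(abs(fit2$components$center_nm - 250), 12)
  expect_equal(classify_association(fit2)$label, "distal")
  expect_error(fit_association(rnorm(10, 135, 30)), "samples")
})

test_that("a 50/50 mixture selects the double model and recovers the far component", {
  set.seed(83)
  d <- c(rnorm(150, 135, 31.9), rnorm(150, 250, 40))
  d <- d[d > 0]
  fit <- fit_association(d)
  expect_equal(fit$model, "double")
  expect_equal(classify_association(fit)$label, "mixed")
  far <- fit$components[fit$components$component == "free", ]
  expect_lt(abs(far$center_nm - 250), 20)
  # independent two-component least-squares oracle on the same histogram
  h <- hist(d, breaks = fit$breaks, plot = FALSE)
  s_cal <- 75 / (2 * sqrt(2 * log(2)))
  gcal <- exp(-(h$mids - 135)^2 / (2 * s_cal^2))
  obj <- function(p) {
    yhat <- p[1] * gcal +
      p[2] * exp(-(h$mids - p[3])^2 / (2 * p[4]^2))
    sum((h$counts - yhat)^2)
  }
  op <- optim(c(max(h$counts), max(h$counts), 260, 45), obj,
              method = "L-BFGS-B", lower = c(0, 0, 100, 5))
  expect_lt(abs(far$center_nm - op$par[3]), 5)
})

test_that("classification rules cover the stated intervals", {
  mk <- function(center) {
    structure(list(model = "single",
                   components = data.frame(component = "single",
                                           center_nm = center,
                                           fwhm_nm = 75, area = 100),
                   calib_center_nm = 135, calib_fwhm_nm = 75),
              class = "association_fit")
  }
  expect_equal(classify_association(mk(140))$label, "intimate")
  expect_equal(classify_association(mk(97.5))$label, "intimate")
  expect_equal(classify_association(mk(172.5))$label, "intimate")
  expect_equal(classify_association(mk(200))$label, "distal")
  expect_equal(classify_association(mk(175))$label, "indeterminate")
  expect_equal(classify_association(mk(180))$label, "indeterminate")
  expect_equal(classify_association(mk(60))$label, "indeterminate")
})

test_that("distribution maps conserve the fitted curve column-wise", {
  set.seed(84)
  fit <- fit_association(rnorm(150, 135, 31.9), model = "single")
  img <- render_distribution_map(fit, extent_nm = 400, pitch_nm = 10)
  xc <- attr(img, "x_nm")
  curve <- forkfoci:::association_curve(fit, xc)
  col_integral <- colSums(img) * 10
  expect_equal(col_integral, curve, tolerance = 1e-6)
  # peak column at the fitted center
  expect_lt(abs(xc[which.max(curve)] - fit$components$center_nm), 10)
  expect_equal(unname(which.max(colSums(img))), unname(which.max(curve)))
  # zero-area fit renders an all-zero map
  fit0 <- fit
  fit0$components$area <- 0
  expect_equal(sum(render_distribution_map(fit0, 400, 10)), 0)
  expect_error(render_distribution_map(fit, extent_nm = -5), "positive")
})

test_that("distances are invariant to rigid translation of the nucleus", {
  cfg <- sim_config(n_foci = 30, cooccupancy = c(A = 0, B = 0, AB = 0.8))
  nuc <- generate_nucleus(cfg, seed = 85)
  an <- analyze_nucleus(nuc$tables, nuc$roi_polygon)
  d0 <- pair_distances(an$clusters$A, an$clusters$B,
                       nadna = an$clusters$nadna)
  shift <- c(4000, -2600)   # whole pixels, so binning is congruent
  tabs <- lapply(nuc$tables, function(tb) {
    tb$x_nm <- tb$x_nm + shift[1]
    tb$y_nm <- tb$y_nm + shift[2]
    tb
  })
  poly <- sweep(nuc$roi_polygon, 2, -shift)
  an2 <- analyze_nucleus(tabs, poly)
  d1 <- pair_distances(an2$clusters$A, an2$clusters$B,
                       nadna = an2$clusters$nadna)
  expect_equal(sort(d1$d_nm), sort(d0$d_nm), tolerance = 1e-9)
})
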