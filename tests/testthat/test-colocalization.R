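test_that("randomization preserves shapes and stays inside the ROI", {
  set.seed(51)
  roi <- rect_roi(2000, 1600)
  cs <- toy_cluster_set(list(block_px(10, 10, 2), block_px(40, 60, 1),
                             rbind(c(5, 80), c(5, 81), c(6, 80))),
                        dim = dim(roi))
  rnd <- randomize_clusters(cs, roi)
  areas0 <- sort(vapply(cs$clusters, `[[`, 1L, "area_px"))
  areas1 <- sort(vapply(rnd$clusters, `[[`, 1L, "area_px"))
  expect_equal(areas1, areas0)
  mask <- as.vector(roi)
  for (cl in rnd$clusters) expect_true(all(mask[cl$px]))
})

test_that("an ROI-sized cluster has exactly one forced placement", {
  roi <- rect_roi(100, 100)                      # 5 x 5 pixels
  cs <- toy_cluster_set(list(as.matrix(expand.grid(i = 1:5, j = 1:5))),
                        dim = c(5, 5))
  for (rep in 1:5) {
    rnd <- randomize_clusters(cs, roi)
    expect_equal(sort(rnd$clusters[[1]]$px), sort(cs$clusters[[1]]$px))
  }
})

test_that("randomized single-pixel positions are uniform over the ROI", {
  set.seed(52)
  roi <- rect_roi(320, 320)                      # 16 x 16 pixels
  cs <- toy_cluster_set(list(cbind(8, 8)), dim = c(16, 16))
  n <- 4000
  cell <- integer(n)
  for (k in seq_len(n)) {
    cl <- randomize_clusters(cs, roi)$clusters[[1]]
    cell[k] <- (ceiling(cl$row / 4) - 1) * 4 + ceiling(cl$col / 4)
  }
  # chi-squared uniformity over a 4x4 partition of the ROI
  p <- chisq.test(tabulate(cell, 16))$p.value
  expect_gt(p, 0.001)
})

test_that("the colocalization factor detects saturation and respects caps", {
  roi <- rect_roi(2000, 2000)
  foci <- toy_cluster_set(list(block_px(10, 10), block_px(30, 30),
                               block_px(50, 50), block_px(70, 70)),
                          dim = dim(roi))
  blanket <- toy_cluster_set(
    list(as.matrix(expand.grid(i = 5:75, j = 5:75))), dim = dim(roi))
  cf <- coloc_factor(foci, blanket, roi, metric = "count", n_sims = 5,
                     seed = 53)
  expect_equal(cf$real, 4)                       # every focus covered
  expect_lte(cf$real, length(foci$clusters))
  expect_gte(cf$factor, 1)
  expect_error(coloc_factor(foci, toy_cluster_set(list(), dim = dim(roi)),
                            roi), "cluster")
})

test_that("a zero null mean is flagged, never silently divided", {
  # disconnected ROI: foci live in a 2x2 left block too small for the 3x3
  # channel-2 cluster, whose only valid placement is the right block
  pitch <- 20
  mask <- matrix(FALSE, 10, 24)
  mask[1:2, 1:2] <- TRUE
  mask[4:6, 20:22] <- TRUE
  roi <- structure(mask, pitch_nm = pitch, origin_nm = c(0, 0),
                   class = c("nucleus_roi", "matrix", "array"))
  foci <- toy_cluster_set(list(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))),
                          dim = dim(mask))
  probe <- toy_cluster_set(list(as.matrix(expand.grid(i = 4:6, j = 20:22))),
                           dim = dim(mask))
  expect_warning(cf <- coloc_factor(foci, probe, roi, n_sims = 3, seed = 54),
                 "undefined")
  expect_true(is.nan(cf$factor))
})

test_that("area metric measures shared pixel area", {
  roi <- rect_roi(1200, 1200)
  a <- toy_cluster_set(list(block_px(10, 10, 2)), dim = dim(roi))  # 5x5
  b <- toy_cluster_set(list(block_px(12, 12, 2)), dim = dim(roi))  # shift 2
  real <- forkfoci:::overlap_measure(a, b, "area")
  expect_equal(real, 9 * 400)                    # 3x3 shared pixels
})

test_that("planted overlaps realize their exact target count", {
  set.seed(55)
  roi <- rect_roi(3000, 3000)
  foci <- toy_cluster_set(lapply(seq(10, 140, by = 13), function(i)
    block_px(i, i, 1)), dim = dim(roi))
  shapes <- toy_cluster_set(lapply(1:15, function(k)
    block_px(20, 20 + 3 * k, 1)), dim = dim(roi))
  for (k in c(0, 3, 7)) {
    planted <- plant_overlaps(foci, shapes, roi, n_overlap = k)
    expect_equal(forkfoci:::overlap_measure(foci, planted, "count"), k)
  }
  expect_error(plant_overlaps(foci, shapes, roi, n_overlap = 99),
               "exceeds")
})

test_that("condition summaries match the closed-form Welch formulas", {
  s <- summarize_condition(c(2, 2, 2), c(1, 1, 1))
  expect_equal(s$delta, 1)
  a <- c(1.3, 2.1, 1.8, 2.6); b <- c(0.9, 1.2, 1.0)
  s2 <- summarize_condition(a, b)
  tt <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(s2$t, tt)
  expect_equal(s2$sem, sd(a) / 2)
  expect_equal(s2$delta_sem, sqrt(var(a) / length(a) + var(b) / length(b)))
  expect_error(summarize_condition(c(1, 2), numeric(0)), "control")
})
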