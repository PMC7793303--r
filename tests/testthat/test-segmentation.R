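make_img <- function(m, pitch = 20) {
  img <- matrix(as.integer(m), nrow(m), ncol(m))
  attr(img, "pitch_nm") <- pitch
  attr(img, "origin_nm") <- c(0, 0)
  class(img) <- c("rendered_image", class(img))
  img
}

test_that("Otsu separates a bimodal image and ignores exterior pixels", {
  set.seed(21)
  roi <- rect_roi(20 * 20, 20 * 10)      # 10 x 20 pixels
  m <- matrix(0L, 10, 20)
  hot <- sample(length(m), 20)           # 10% of pixels at value 10
  m[hot] <- 10L
  thr <- otsu_in_roi(make_img(m), roi)
  # foreground is strictly above threshold, so the two-valued image puts
  # the threshold at the background value and selects the hot 10%
  expect_gte(thr, 0)
  expect_lt(thr, 10)
  fg <- m > thr
  expect_equal(which(fg), sort(hot))
  # randomizing pixels outside the ROI must not change the threshold
  roi_half <- roi
  roi_half[, 11:20] <- FALSE
  thr1 <- otsu_in_roi(make_img(m), roi_half)
  m2 <- m
  m2[, 11:20] <- sample(0:50, 100, replace = TRUE)
  expect_identical(otsu_in_roi(make_img(m2), roi_half), thr1)
  # constant image has no threshold
  expect_error(otsu_in_roi(make_img(matrix(3L, 10, 20)), roi), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance oracle", {
  set.seed(22)
  roi <- rect_roi(20 * 16, 20 * 16)
  for (rep in 1:25) {
    v <- sample(0:15, 256, replace = TRUE,
                prob = runif(16)^sample(1:3, 1))
    if (min(v) == max(v)) next
    m <- matrix(v, 16, 16)
    expect_identical(otsu_in_roi(make_img(m), roi), otsu_oracle(v))
  }
})

test_that("a single synthetic focus segments to one cluster at its center", {
  set.seed(23)
  ctr <- c(500, 460)
  tab <- loc_tab(rnorm(300, ctr[1], 40), rnorm(300, ctr[2], 40))
  roi <- rect_roi(1000, 1000)
  img <- render(tab, 20, c(0, 1000, 0, 1000))
  cs <- segment_clusters(img, roi, min_area_px = 5)
  expect_equal(length(cs), 1)
  expect_lt(abs(cs$clusters[[1]]$com_nm[["x"]] - ctr[1]), 20)
  expect_lt(abs(cs$clusters[[1]]$com_nm[["y"]] - ctr[2]), 20)
  # localization bookkeeping never exceeds the channel total
  expect_lte(sum(vapply(cs$clusters, `[[`, 1, "n_locs")), nrow(tab))
})

test_that("well separated foci stay separate; touching foci merge", {
  set.seed(24)
  roi <- rect_roi(4000, 1000)
  two <- loc_tab(c(rnorm(300, 800, 40), rnorm(300, 2800, 40)),
                 rnorm(600, 500, 40))
  cs2 <- segment_clusters(render(two, 20, c(0, 4000, 0, 1000)), roi,
                          min_area_px = 5)
  expect_equal(length(cs2), 2)
  near <- loc_tab(c(rnorm(300, 800, 40), rnorm(300, 820, 40)),
                  rnorm(600, 500, 40))
  cs1 <- segment_clusters(render(near, 20, c(0, 4000, 0, 1000)), roi,
                          min_area_px = 5)
  expect_equal(length(cs1), 1)
})

test_that("an empty image yields an empty cluster set", {
  roi <- rect_roi(400, 400)
  img <- render(loc_tab(numeric(0), numeric(0)), 20, c(0, 400, 0, 400))
  cs <- segment_clusters(img, roi)
  expect_equal(length(cs), 0)
  expect_equal(nrow(as.data.frame(cs)), 0)
})

test_that("labeling uses 8-connectivity", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 5L; m[3, 3] <- 5L   # diagonal neighbors
  m[5, 5] <- 5L                  # separate
  roi <- rect_roi(120, 120)
  cs <- segment_clusters(make_img(m), roi, min_area_px = 1, threshold = 0)
  expect_equal(length(cs), 2)
  areas <- sort(vapply(cs$clusters, `[[`, 1L, "area_px"))
  expect_equal(areas, c(1L, 2L))
})

test_that("segmentation is idempotent on its own foreground mask", {
  set.seed(25)
  roi <- rect_roi(2000, 2000)
  tab <- loc_tab(rnorm(600, 700, 50), rnorm(600, 900, 50))
  img <- render(tab, 20, c(0, 2000, 0, 2000))
  cs <- segment_clusters(img, roi, min_area_px = 2)
  fg <- matrix(0L, nrow(img), ncol(img))
  for (cl in cs$clusters) fg[cl$px] <- 1L
  cs2 <- segment_clusters(make_img(fg), roi, min_area_px = 2, threshold = 0)
  expect_equal(length(cs2), length(cs))
  expect_setequal(
    lapply(cs2$clusters, function(cl) sort(cl$px)),
    lapply(cs$clusters, function(cl) sort(cl$px)))
})

test_that("cluster overlap equals brute-force set intersection", {
  set.seed(26)
  dimg <- c(40, 40)
  for (rep in 1:10) {
    a_px <- block_px(sample(5:35, 1), sample(5:35, 1), half = sample(1:3, 1))
    b_px <- block_px(sample(5:35, 1), sample(5:35, 1), half = sample(1:3, 1))
    cs <- toy_cluster_set(list(a_px, b_px), dimg)
    ov <- cluster_overlap(cs$clusters[[1]], cs$clusters[[2]])
    # oracle: count coordinate pairs present in both pixel lists
    key <- function(m) paste(m[, 1], m[, 2])
    expect_equal(ov$px, length(intersect(key(a_px), key(b_px))))
    expect_equal(ov$area_nm2, ov$px * 400)
  }
  cs <- toy_cluster_set(list(block_px(10, 10), block_px(10, 10)), dimg)
  expect_equal(cluster_overlap(cs$clusters[[1]], cs$clusters[[2]])$px, 9)
  cs2 <- toy_cluster_set(list(block_px(5, 5), block_px(30, 30)), dimg)
  expect_equal(cluster_overlap(cs2$clusters[[1]], cs2$clusters[[2]])$px, 0)
})
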