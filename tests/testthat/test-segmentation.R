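test_that("polygon rasterization follows the boundary-inclusive even-odd rule", {
  # axis-aligned rectangle with corners (10,10)-(19,19): exactly 100 pixels
  rect <- rbind(c(10, 10), c(10, 19), c(19, 19), c(19, 10))
  m <- rasterize_polygon(rect, c(64, 64))
  expect_equal(sum(m), 100)
  expect_equal(sum(m[11:20, 11:20]), 100)

  # triangle agrees with the brute-force even-odd scan
  tri <- rbind(c(0, 0), c(0, 4), c(4, 0))
  expect_identical(rasterize_polygon(tri, c(8, 8)), oracle_rasterize(tri, c(8, 8)))

  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), c(8, 8)), ">= 3")
  expect_warning(out <- rasterize_polygon(rbind(c(1, 1), c(1, 1), c(1, 1)),
                                          c(8, 8)), "zero-area")
  expect_equal(sum(out), 0)
})

test_that("rasterization matches the exhaustive oracle on random polygons", {
  set.seed(7)
  for (i in 1:100) {
    dims <- c(sample(16:32, 1), sample(16:32, 1))
    poly <- random_simple_polygon(dims)
    expect_identical(rasterize_polygon(poly, dims), oracle_rasterize(poly, dims),
                     label = sprintf("polygon %d", i))
  }
})

test_that("thresholding selects >= cutoff within the ROI only", {
  img <- matrix(0, 4, 4)
  roi <- matrix(0L, 4, 4)
  img[1, 1:4] <- c(10, 20, 30, 40)
  roi[1, 1:4] <- 1L
  img[3, 3] <- 1000  # bright pixel outside the ROI must never be selected

  m <- threshold_within_roi(img, roi, threshold_rule("absolute", 25))
  expect_equal(sum(m), 2)
  expect_true(all(m <= roi))

  # nearest-rank 50th percentile of {10,20,30,40} is 20 -> 3 pixels selected
  m50 <- threshold_within_roi(img, roi, threshold_rule("percentile-within-roi", 50))
  vals <- img[roi == 1]
  cutoff <- sort(vals)[ceiling(0.5 * length(vals))]
  expect_equal(cutoff, 20)
  brute <- (roi == 1) & (img >= cutoff)
  expect_equal(m50 == 1, brute)
  expect_equal(sum(m50), 3)

  # cutoff at the ROI minimum selects the whole ROI
  expect_equal(threshold_within_roi(img, roi, threshold_rule("absolute", 10)),
               roi)
  # constant image: any percentile selects the entire ROI (>= tie rule)
  expect_equal(threshold_within_roi(matrix(5, 4, 4), roi,
                                    threshold_rule("percentile-within-roi", 100)),
               roi)
  expect_error(threshold_within_roi(img, matrix(0L, 4, 4),
                                    threshold_rule("absolute", 1)), "empty")
  expect_error(threshold_rule("percentile-within-roi", 101), "\\[0, 100\\]")
})

test_that("thresholded masks are subsets of their ROI on random images", {
  set.seed(11)
  for (i in 1:20) {
    img <- matrix(runif(400, 0, 100), 20, 20)
    roi <- oracle_rasterize(random_simple_polygon(c(20, 20)), c(20, 20))
    if (sum(roi) == 0) next
    rule <- if (i %% 2) threshold_rule("absolute", runif(1, 0, 100))
            else threshold_rule("percentile-within-roi", runif(1, 0, 100))
    m <- threshold_within_roi(img, roi, rule)
    expect_true(all(m <= roi))
  }
})

test_that("region growing returns the seed's 4-connected component", {
  # constant image, tolerance 0: everything is reachable
  expect_equal(sum(region_grow(matrix(7, 6, 9), c(2, 3), 0)), 54)

  # two bright blobs on dark background: only the seeded blob grows
  img <- matrix(0, 16, 16)
  img[3:6, 3:6] <- 100
  img[10:13, 10:13] <- 100
  m <- region_grow(img, c(4, 4), 5)
  expect_identical(m, oracle_flood_fill(img, c(4, 4), 5))
  expect_equal(sum(m), 16)
  expect_equal(sum(m[11:14, 11:14]), 0)

  # random images against the BFS oracle
  set.seed(13)
  for (i in 1:15) {
    ri <- matrix(sample(1:5, 144, TRUE), 12, 12)
    seed <- c(sample(0:11, 1), sample(0:11, 1))
    tol <- sample(0:2, 1)
    expect_identical(region_grow(ri, seed, tol), oracle_flood_fill(ri, seed, tol))
  }

  expect_error(region_grow(matrix(0, 4, 4), c(9, 0), 1), "outside")
  expect_error(region_grow(matrix(0, 4, 4), c(1, 1), -1), ">= 0")
})

test_that("apply_roi_set composes annotations in order", {
  stack <- image_stack(array(50, c(24, 24, 3)), c(1, 1), 6)
  rect <- rbind(c(5, 5), c(5, 10), c(10, 10), c(10, 5))
  anns <- lapply(0:2, function(s) list(slice = s, type = "polygon",
                                       vertices = rect))
  masks <- apply_roi_set(stack, roi_set(anns))
  expect_true(is_mask_stack(masks))
  for (i in 0:2) expect_equal(sum(get_slice(masks, i)), 36)
  expect_equal(slice_spacing(masks), slice_spacing(stack))

  # erase covering its polygon leaves nothing
  erased <- apply_roi_set(stack, roi_set(list(
    anns[[1]],
    list(slice = 0, type = "erase_polygon",
         vertices = rbind(c(4, 4), c(4, 11), c(11, 11), c(11, 4))))))
  expect_equal(sum(get_slice(erased, 0)), 0)

  # overlapping polygons form a union, idempotently
  shifted <- rect + 3
  uni <- apply_roi_set(stack, roi_set(list(
    anns[[1]], list(slice = 0, type = "polygon", vertices = shifted))))
  m1 <- rasterize_polygon(rect, c(24, 24))
  m2 <- rasterize_polygon(shifted, c(24, 24))
  expect_equal(get_slice(uni, 0), pmax(m1, m2))
  expect_lte(sum(get_slice(uni, 0)), sum(m1) + sum(m2))

  # order of additive annotations does not matter
  set.seed(17)
  polys <- lapply(1:4, function(i) list(slice = 0, type = "polygon",
                                        vertices = random_simple_polygon(c(24, 24))))
  a <- apply_roi_set(stack, roi_set(polys))
  b <- apply_roi_set(stack, roi_set(polys[sample(4)]))
  expect_identical(a$data, b$data)

  # seed annotations grow from the image intensities
  img <- array(0, c(16, 16, 1)); img[4:8, 4:8, 1] <- 100
  s2 <- image_stack(img, c(1, 1), 6)
  grown <- apply_roi_set(s2, roi_set(list(
    list(slice = 0, type = "seed", seed = c(5, 5), tolerance = 10))))
  expect_equal(sum(get_slice(grown, 0)), 25)
})
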