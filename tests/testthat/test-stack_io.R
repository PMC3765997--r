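test_that("raw dialect round-trip is bit-exact on random stacks", {
  set.seed(101)
  for (i in 1:8) {
    s <- random_stack(dims = c(sample(3:10, 1), sample(3:10, 1), sample(2:6, 1)))
    path <- tempfile()
    write_stack(s, path, format = "raw")
    r <- read_stack(path)
    expect_identical(r$data, s$data)
    expect_identical(r$pixel_spacing, s$pixel_spacing)
    expect_identical(r$slice_thickness, s$slice_thickness)
    expect_identical(r$slice_gap, s$slice_gap)
    expect_identical(r$subject_id, s$subject_id)
  }
})

test_that("NIfTI round-trip preserves voxels, spacing and thickness/gap", {
  set.seed(102)
  s <- image_stack(array(runif(20 * 18 * 20), c(20, 18, 20)),
                   pixel_spacing = c(1.5, 1.5), slice_thickness = 6,
                   slice_gap = 0.5)
  path <- tempfile(fileext = ".nii.gz")
  write_stack(s, path)
  r <- read_stack(path)
  expect_equal(r$data, s$data, tolerance = 1e-7)
  expect_equal(r$pixel_spacing, c(1.5, 1.5))
  expect_equal(r$slice_thickness, 6)
  expect_equal(r$slice_gap, 0.5)
  expect_equal(n_slices(r), 20)
  # mask stacks stay exactly binary through NIfTI
  m <- image_stack(array(sample(0:1, 8 * 8 * 3, TRUE), c(8, 8, 3)), c(1, 1), 6)
  write_stack(m, path)
  expect_true(all(read_stack(path)$data %in% c(0, 1)))
})

test_that("degenerate and malformed stacks are rejected", {
  expect_error(image_stack(array(0, c(4, 4, 0)), c(1, 1)), "at least one slice")
  expect_error(image_stack(list(), c(1, 1)), "at least one slice")
  expect_error(image_stack(array(0, c(4, 4, 2)), c(1, -1)), "positive")
  expect_error(image_stack(array(0, c(4, 4, 2)), c(1, 1), slice_thickness = 0),
               "positive")
  expect_error(image_stack(list(matrix(0, 2, 2), matrix(0, 3, 3)), c(1, 1)),
               "identical")
  expect_error(read_stack(tempfile(fileext = ".nii")), "no such file")
})

test_that("geometry metadata is mandatory on read", {
  # raw header with geometry fields stripped
  s <- random_stack(c(4, 4, 2), seed = 1)
  path <- tempfile()
  write_stack(s, path, "raw")
  h <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h$pixel_spacing <- NULL
  jsonlite::write_json(h, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "geometry missing")
  # unknown schema version
  h2 <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h2$version <- 99
  jsonlite::write_json(h2, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "version")
})

test_that("slice centers sit at i * (thickness + gap)", {
  s <- image_stack(array(0, c(2, 2, 5)), c(1, 1), slice_thickness = 6,
                   slice_gap = 1.5)
  expect_equal(slice_z(s, 0:4), 0:4 * 7.5)
  expect_equal(slice_spacing(s), 7.5)
})

test_that("ROI sets round-trip through versioned JSON and validate on bind", {
  tri <- list(slice = 0, type = "polygon",
              vertices = rbind(c(0, 0), c(0, 4), c(4, 0)))
  sd_ann <- list(slice = 1, type = "seed", seed = c(2, 3), tolerance = 1.5)
  er <- list(slice = 0, type = "erase_polygon",
             vertices = rbind(c(1, 1), c(1, 2), c(2, 2)), label = "atrial")
  r <- roi_set(list(tri, sd_ann, er))
  path <- tempfile(fileext = ".json")
  write_roi_set(r, path)
  r2 <- read_roi_set(path)
  expect_length(r2$annotations, 3)
  # order and payloads preserved
  expect_equal(vapply(r2$annotations, `[[`, "", "type"),
               c("polygon", "seed", "erase_polygon"))
  expect_equal(r2$annotations[[1]]$vertices, tri$vertices)
  expect_equal(r2$annotations[[2]]$seed, c(2, 3))
  expect_equal(r2$annotations[[2]]$tolerance, 1.5)
  expect_equal(r2$annotations[[3]]$label, "atrial")

  expect_error(roi_set(list(list(slice = 0, type = "polygon",
                                 vertices = rbind(c(0, 0), c(1, 1))))),
               ">= 3")
  # unknown version rejected
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$version <- 2
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_roi_set(path), "version")

  stack <- image_stack(array(0, c(10, 10, 10)), c(1, 1))
  expect_silent(validate_roi_binding(r, stack))
  bad <- roi_set(list(modifyList(tri, list(slice = 99))))
  expect_error(validate_roi_binding(bad, stack), "slice 99")
  oob <- roi_set(list(modifyList(tri, list(vertices = rbind(c(0, 0), c(0, 40), c(4, 0))))))
  expect_error(validate_roi_binding(oob, stack), "outside")
})

test_that("packaged paired table reproduces the published masses", {
  tab <- read_paired_table(table1_path())
  expect_s3_class(tab, "pat_paired_table")
  expect_equal(nrow(tab), 27)               # 9 subjects x 3 quantities
  expect_equal(attr(tab, "methods"), c("autopsy_g", "cmr_g"))
  expect_equal(tab$autopsy_g[tab$subject == 1 & tab$quantity == "total"], 235)
  expect_equal(tab$cmr_g[tab$subject == 9 & tab$quantity == "atrial"], 23)
  # hand-summed column checks
  expect_equal(sum(tab$autopsy_g[tab$quantity == "total"]), 2341)
  expect_equal(sum(tab$cmr_g[tab$quantity == "atrial"]), 331)
})

test_that("malformed paired tables are rejected with row references", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject,quantity,autopsy_g,cmr_g",
               "1,total,235,279", "2,total,abc,302"), path)
  expect_error(read_paired_table(path), "non-numeric.*row 3")
  # a single-subject table loads, but agreement computations reject it
  writeLines(c("subject,quantity,autopsy_g,cmr_g", "1,total,235,279"), path)
  tab <- read_paired_table(path)
  expect_equal(nrow(tab), 1)
  expect_error(agreement_report(tab), "fewer than 2")
})
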