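# Domain types and readers/writers.

test_that("volumetric_image enforces its invariants", {
  expect_error(volumetric_image(matrix(0, 2, 2), c(1, 1, 1)), "3 axes")
  expect_error(volumetric_image(array(0, c(2, 2, 2)), c(1, 0, 1)),
               "positive")
  img <- volumetric_image(array(0, c(4, 3, 2)), c(0.5, 0.5, 2),
                          c(1, 2, 3), "NP")
  expect_identical(dim(img), c(4L, 3L, 2L))
  expect_identical(img$channel_label, "NP")
})

test_that("voxel/physical conversion is a bijection and honours spacing", {
  img <- ramp_image(c(10L, 12L, 5L), spacing = c(0.5, 0.5, 2.0))
  set.seed(1)
  idx <- cbind(runif(100, 0, 9), runif(100, 0, 11), runif(100, 0, 4))
  roundtrip <- phys_to_voxel(img, voxel_to_phys(img, idx))
  expect_lt(max(abs(roundtrip - idx)), 1e-9)
  # physical position of voxel (i,j,k) = origin + index * spacing
  expect_equal(as.numeric(voxel_to_phys(img, cbind(2, 3, 1))),
               c(2 * 0.5, 3 * 0.5, 1 * 2.0))
})

test_that("brain_scan requires NP and consistent channel grids", {
  np <- ramp_image()
  nt <- ramp_image()
  expect_error(brain_scan("s", list(NT = nt)), "NP channel")
  bad <- volumetric_image(array(0, c(6, 5, 4)), c(1, 1, 1))
  expect_error(brain_scan("s", list(NP = np, NT = bad)), "geometry")
  expect_s3_class(brain_scan("s", list(NP = np, NT = nt)), "brain_scan")
})

test_that("TIFF roundtrip preserves data, type and spacing", {
  img <- ramp_image(c(8L, 6L, 100L), spacing = c(0.5, 0.5, 2.0))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(img, path)
  back <- read_stack(path, channel_label = "NP")
  expect_identical(dim(back), dim(img))
  expect_equal(back$data, img$data)            # 8-bit values exact
  expect_equal(back$spacing, img$spacing, tolerance = 1e-5)

  # float volume roundtrips through 32-bit TIFF
  f <- volumetric_image(array(runif(60), c(5, 4, 3)) + 0.25,
                        c(1, 1, 1.5))
  pf <- withr::local_tempfile(fileext = ".tif")
  write_stack(f, pf)
  backf <- read_stack(pf)
  expect_equal(backf$data, f$data, tolerance = 1e-6)
})

test_that("NRRD roundtrip is bit-identical for float data", {
  f <- volumetric_image(array(rnorm(210), c(7, 6, 5)), c(0.5, 0.5, 2),
                        c(1, -2, 3))
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_stack(f, path)
  back <- read_stack(path)
  expect_identical(back$data, f$data)
  expect_equal(back$spacing, f$spacing)
  expect_equal(back$origin, f$origin)

  # displacement-field (4D) roundtrip
  df <- displacement_field(array(rnorm(7 * 6 * 5 * 3), c(7, 6, 5, 3)),
                           c(0.5, 0.5, 2))
  pf <- withr::local_tempfile(fileext = ".nrrd")
  write_displacement_field(df, pf)
  back2 <- read_displacement_field(pf)
  expect_identical(back2$vectors, df$vectors)
})

test_that("readers reject missing, 2D-only and truncated files", {
  expect_error(read_stack("no/such/file.tif"), "no such file")
  img <- ramp_image(c(4L, 4L, 3L))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_stack(img, p)
  raw <- readBin(p, "raw", file.info(p)$size)
  writeBin(raw[1:(length(raw) - 10)], p)
  expect_error(read_stack(p), "truncated")
  # single-page TIFF is not a volume
  one <- volumetric_image(array(1:12, c(4, 3, 1)), c(1, 1, 1))
  pt <- withr::local_tempfile(fileext = ".tif")
  larvreg:::write_tiff_stack(one, pt)
  expect_error(read_stack(pt), "2D-only")
})

test_that("TIFF without z metadata errors unless spacing is supplied", {
  img <- ramp_image(c(6L, 5L, 4L))
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack(img, p)
  raw <- readBin(p, "raw", file.info(p)$size)
  # blank out the spacing entry in the ImageJ description
  pos <- grepRaw("spacing=", raw, fixed = TRUE)
  raw[pos:(pos + 7)] <- charToRaw("spacink=")
  writeBin(raw, p)
  expect_error(read_stack(p), "spacing")
  back <- read_stack(p, spacing = c(0.5, 0.5, 2.0))
  expect_equal(back$data, img$data)
})

test_that("landmark tables roundtrip with order preserved", {
  set <- landmark_set(c("b point", "a point", "c"),
                      rbind(c(1.5, 2, 3), c(-1, 0.25, 7), c(0, 0, 0)),
                      "subject1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(set, p)
  back <- read_landmarks(p, "subject1")
  expect_identical(back$label, set$label)
  expect_equal(lm_coords(back), lm_coords(set))

  empty <- landmark_set(character(0), matrix(numeric(0), 0, 3))
  pe <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(empty, pe)
  expect_identical(nrow(read_landmarks(pe)), 0L)
})

test_that("landmark validation catches duplicates and bad coordinates", {
  expect_error(landmark_set(c("a", "a"), rbind(c(0, 0, 0), c(1, 1, 1))),
               "duplicate")
  expect_error(landmark_set("a", rbind(c(NA, 0, 0))), "finite")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x_um,y_um,z_um", "a,1,2,3", "a,4,5,6"), p)
  expect_error(read_landmarks(p), "duplicate")
})

test_that("the gold-standard schema has 30 unique labels incl. anchors", {
  labs <- gold_standard_labels()
  expect_length(labs, 30L)
  expect_false(anyDuplicated(labs) > 0)
  expect_true("left antennal nerve" %in% labs)
  expect_true(all(unlist(qa_anchor_labels()) %in% labs))
})

test_that("Fiji point lists import with and without labels", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# exported points", "Point_1\t10.5\t20\t4",
               "Point_2\t11\t21\t6"), p)
  s <- import_fiji_points(p)
  expect_identical(s$label, c("Point_1", "Point_2"))
  expect_equal(s$x, c(10.5, 11))
  writeLines(c("1.0 2.0 3.0", "4 5 6"), p)
  s2 <- import_fiji_points(p)
  expect_identical(s2$label, c("P1", "P2"))
})

test_that("QA report JSON roundtrips and enforces its invariants", {
  r <- qa_report("s1", vi = 80, ti = 40, m_score = 80, s_score = 50)
  expect_identical(r$decision, "flagged")
  expect_error(qa_report("s1", 80, 42, 80, 50), "M \\* S")
  p <- withr::local_tempfile(fileext = ".json")
  write_qa_report(r, p)
  back <- read_qa_report(p)
  expect_equal(back$ti, r$ti)
  expect_identical(back$decision, "flagged")
})
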