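test_that("marker model has the 39 full-body labels with a side partition", {
  m <- marker_model()
  expect_length(m$required_labels, 39L)
  expect_setequal(c(m$side_map$left, m$side_map$right, m$side_map$midline),
                  m$required_labels)
  expect_true(all(c("LASI", "RASI", "LHEE", "RTOE", "C7", "RBAK") %in%
                    m$required_labels))
})

test_that("CSV round trip preserves positions and column layout", {
  set <- standing_set(n_frames = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers(set, path, model = marker_model())
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  hdr <- gsub('"', "", hdr)
  expect_identical(hdr[1], "frame")
  expect_identical(hdr[2:4], c("LFHD_x", "LFHD_y", "LFHD_z"))
  back <- read_markers(path, rate = set$rate)
  expect_equal(back$n_frames, 10L)
  expect_equal(back$rate, 100)
  for (lb in names(set$markers))
    expect_equal(back$markers[[lb]], set$markers[[lb]], tolerance = 1e-7,
                 ignore_attr = TRUE)
})

test_that("millimetre files normalize to the same set as metre files", {
  set <- standing_set(n_frames = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  mm <- set
  for (lb in names(mm$markers)) mm$markers[[lb]] <- mm$markers[[lb]] * 1000
  write_markers(mm, path)
  back <- read_markers(path, units = "mm")
  expect_equal(back$markers$LASI, set$markers$LASI, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a missing required label is reported by name", {
  set <- standing_set(n_frames = 5)
  set$markers$LASI <- NULL
  set$missing_mask <- set$missing_mask[, colnames(set$missing_mask) != "LASI"]
  path <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(write_markers(set, path))
  expect_error(read_markers(path), "LASI")
  expect_error(read_markers("/nonexistent/file.csv"), "cannot read")
})

test_that("degenerate writes and missing samples are handled explicitly", {
  one <- marker_set(list(M = matrix(1, 1, 3)), rate = 100)
  expect_error(write_markers(one, tempfile()), "2 frames")
  m <- matrix(rnorm(30), 10, 3)
  m[4, ] <- NA
  set <- marker_set(list(M = m), rate = 100)
  expect_true(set$missing_mask[4, "M"])
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers(set, path)
  back <- read_markers(path, model = NULL)
  expect_true(back$missing_mask[4, "M"])
  expect_false(any(back$missing_mask[-4, "M"]))
})

test_that("validate_trial reports gaps, rate mismatch, and a clean bill", {
  set <- standing_set(n_frames = 50)
  expect_identical(nrow(validate_trial(set)), 0L)
  gappy <- set
  gappy$markers$RHEE[1:10, ] <- NA
  gappy$missing_mask[1:10, "RHEE"] <- TRUE
  rep <- validate_trial(gappy)
  row <- rep[rep$issue == "gaps" & rep$detail == "RHEE", ]
  expect_equal(row$value, 0.20)
  fast <- standing_set(rate = 120)
  rep2 <- validate_trial(fast)
  expect_true("rate_mismatch" %in% rep2$issue)
})

test_that("metadata tables round-trip through the TSV carrier", {
  df <- data.frame(subject_id = c("S1", "S2"), group = c("control", "pd"),
                   inner_side = c("left", "right"), age = c(68, 71),
                   sex = c("F", "M"), height = c(160, 171),
                   bmi = c(23.1, 25.9), updrs_total = c(NA, 44))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(df, path)
  back <- read_metadata(path)
  expect_equal(back$subject_id, df$subject_id)
  expect_equal(back$updrs_total, df$updrs_total)
})
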