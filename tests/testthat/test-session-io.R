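test_that("session JSON round-trips byte-identically after canonical write", {
  for (k in 1:10) {
    s <- make_session(sprintf("P%03d", k), seed = 100 + k,
                      with_ball = k %% 2 == 0)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    writeSession(s, f1)
    s2 <- readSession(f1)
    writeSession(s2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("reader preserves samples and attaches recorded ball positions", {
  s <- make_session("P7", seed = 7, with_ball = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  writeSession(s, f)
  s2 <- readSession(f)
  expect_equal(length(s2@single@t), 600)
  expect_equal(s2@single@accel, s@single@accel, ignore_attr = TRUE)
  expect_equal(s2@dualBall$x, s@dualBall$x)
  expect_equal(taskCondition(s2@dual), "dual")
})

test_that("single-trial files parse into sessions with the other trial absent", {
  s <- Session("solo", single = make_recording(2000, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  writeSession(s, f)
  s2 <- readSession(f)
  expect_equal(length(s2@single@t), 2000)
  expect_null(s2@dual)
})

test_that("structural and ordering violations are errors, never silent fixes", {
  s <- make_session("bad", seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeSession(s, f)
  js <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  # non-monotone timestamps in the dual trial
  js_bad <- js
  js_bad$trials[[2]]$samples[[3]]$t <- js_bad$trials[[2]]$samples[[2]]$t
  jsonlite::write_json(js_bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(readSession(f), "non-monotone")
  # missing sample key
  js_bad <- js
  js_bad$trials[[1]]$samples <- lapply(js_bad$trials[[1]]$samples,
                                       function(x) x[names(x) != "gz"])
  jsonlite::write_json(js_bad, f, auto_unbox = TRUE, digits = NA)
  expect_error(readSession(f), "gz")
  # no trials at all
  jsonlite::write_json(list(participant_id = "x", trials = list()), f,
                       auto_unbox = TRUE)
  expect_error(readSession(f), "trials")
  # malformed JSON names the file
  writeLines("{ not json", f)
  expect_error(readSession(f), "malformed JSON")
})

test_that("per-channel array variant and unit conversion are accepted", {
  rec <- make_recording(300, seed = 5)
  obj <- list(participant_id = "arr",
              trials = list(list(
                condition = "single",
                samples = list(t = rec@t,
                               ax = rec@accel[, 1] / 9.80665,
                               ay = rec@accel[, 2] / 9.80665,
                               az = rec@accel[, 3] / 9.80665,
                               gx = rec@gyro[, 1] * pi / 180,
                               gy = rec@gyro[, 2] * pi / 180,
                               gz = rec@gyro[, 3] * pi / 180))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  s <- readSession(f, convert_units = TRUE)
  expect_equal(s@single@accel, rec@accel, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s@single@gyro, rec@gyro, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("metadata reader validates cohorts and collects range warnings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,age,sex,cohort,mmse_total,ravlt_total,ravlt_long_delay,faq_total",
    "A,70,male,healthy,29,50,10,1",
    "B,75,female,MCI,26,40,5,4",
    "C,80,female,ADRD,22,25,2,12"), f)
  md <- readMetadata(f)
  expect_equal(nrow(md), 3)
  expect_equal(as.character(md$cohort), c("healthy", "MCI", "ADRD"))

  # an empty cohort cell is a retained participant with cohort "missing"
  writeLines(c(
    "participant_id,age,sex,cohort,mmse_total,ravlt_total,ravlt_long_delay,faq_total",
    "A,70,male,,29,50,10,1"), f)
  md <- readMetadata(f)
  expect_equal(as.character(md$cohort), "missing")

  # unknown cohort tokens list the allowed values
  writeLines(c(
    "participant_id,age,sex,cohort,mmse_total,ravlt_total,ravlt_long_delay,faq_total",
    "A,70,male,dementia,29,50,10,1"), f)
  expect_error(readMetadata(f), "healthy, MCI, ADRD")

  # out-of-protocol age: warning collected, record kept
  writeLines(c(
    "participant_id,age,sex,cohort,mmse_total,ravlt_total,ravlt_long_delay,faq_total",
    "A,59,male,healthy,29,50,10,1"), f)
  md <- readMetadata(f, strict_range = TRUE)
  expect_equal(nrow(md), 1)
  expect_match(attr(md, "range_warnings"), "59")
})

test_that("metadata CSV writer round-trips", {
  md <- make_metadata(5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeMetadata(md, f)
  md2 <- readMetadata(f)
  expect_equal(md2$age, md$age)
  expect_equal(as.character(md2$cohort), md$cohort)
})
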