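test_that("cop_trace validates sampling, length and finiteness", {
  tr <- cop_trace(time = c(0, 0.02, 0.04), ap = c(0, 0.01, 0),
                  ml = c(0, 0, 0))
  expect_s3_class(tr, "cop_trace")
  expect_equal(sampling_rate(tr), 50)

  expect_error(cop_trace(0, 0, 0), class = "sot_degenerate_error")
  expect_error(cop_trace(c(0, 0.02, 0.07), c(0, 0, 0), c(0, 0, 0)),
               class = "sot_sampling_error")
  expect_error(cop_trace(c(0, 0.02), c(0, NaN), c(0, 0)),
               class = "sot_validation_error")
  expect_error(cop_trace(c(0, 0.02, 0.01), c(0, 0, 0), c(0, 0, 0)),
               class = "sot_sampling_error")
})

test_that("read_cop_trace infers fs, converts units and flags bad files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ap,ml", "0,0,0", "0.02,0.01,0", "0.04,0,0"), f)
  tr <- read_cop_trace(f)
  expect_equal(sampling_rate(tr), 50)
  expect_equal(tr$ap, c(0, 0.01, 0))

  # case-insensitive header, unit conversion to metres
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,AP,ML", "0,1,0", "0.02,2,0", "0.04,0,0"), f2)
  tr2 <- read_cop_trace(f2, units = "cm")
  expect_equal(tr2$ap, c(0.01, 0.02, 0))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ap", "0,0", "0.02,0"), f3)
  expect_error(read_cop_trace(f3), class = "sot_format_error")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ap,ml", "0,0,0", "0.02,0,0", "0.07,0,0"), f4)
  expect_error(read_cop_trace(f4), class = "sot_sampling_error")

  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ap,ml", "0,0,0"), f5)
  expect_error(read_cop_trace(f5), class = "sot_degenerate_error")

  expect_error(read_cop_trace(file.path(tempdir(), "nope.csv")),
               class = "sot_io_error")
})

test_that("write/read round trip preserves samples to 1e-9", {
  withr::with_seed(42, {
    tr <- make_trace(ap = rnorm(1000, 0, 0.01), ml = rnorm(1000, 0, 0.01))
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_cop_trace(tr, f)
  back <- read_cop_trace(f)
  expect_equal(back$ap, tr$ap, tolerance = 1e-9)
  expect_equal(back$ml, tr$ml, tolerance = 1e-9)
  expect_equal(back$time, tr$time, tolerance = 1e-9)
  expect_equal(sampling_rate(back), 50)

  bad <- data.frame(time = c(0, 0.02), ap = c(0, NaN), ml = c(0, 0))
  expect_error(write_cop_trace(bad, withr::local_tempfile()),
               class = "sot_validation_error")
})

test_that("sot_study enforces its invariants", {
  p <- tibble::tibble(pid = "P1", height = 1.7)
  tr <- make_trace(rep(c(0.001, -0.001), 50))
  good <- tibble::tibble(pid = "P1", condition = "SOT1", device = "vr",
                         trial_index = 1L, ei = NA_real_, trace = list(tr))
  expect_s3_class(sot_study(p, good), "sot_study")

  expect_error(sot_study(tibble::tibble(pid = "P1", height = 3), good),
               class = "sot_study_error")
  expect_error(
    sot_study(p, dplyr::mutate(good, pid = "P9")),
    class = "sot_study_error")
  expect_error(
    sot_study(p, dplyr::bind_rows(good, good)),
    class = "sot_study_error")
  expect_error(
    sot_study(p, tibble::tibble(pid = "P1", condition = "SOT1",
                                device = "equitest", trial_index = 1L,
                                ei = 140, trace = list(NULL))),
    class = "sot_study_error")
})

test_that("a study round-trips through manifest + CSVs, order-independently", {
  st <- simulate_study(sim_config(n_participants = 2), seed = 5)
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))

  back <- load_study(manifest)
  expect_equal(nrow(back$trials), nrow(st$trials))
  expect_equal(nrow(back$trials), 2 * 28)
  expect_equal(back$participants$height, st$participants$height)
  expect_equal(back$trials$ei, st$trials$ei)
  i <- which(back$trials$device == "vr")[1]
  expect_equal(back$trials$trace[[i]]$ap, st$trials$trace[[i]]$ap,
               tolerance = 1e-9)

  # permuting manifest entries yields the same study
  m <- yaml::read_yaml(manifest)
  m$trials <- rev(m$trials)
  m$participants <- rev(m$participants)
  manifest2 <- file.path(dir, "manifest2.yaml")
  yaml::write_yaml(m, manifest2)
  back2 <- load_study(manifest2)
  expect_equal(back2$trials$ei, back$trials$ei)
  expect_equal(back2$participants, back$participants)
})

test_that("manifest errors: orphan pid, missing fields, empty manifest", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.yaml")
  yaml::write_yaml(list(
    participants = list(list(pid = "P1", height = 1.7)),
    trials = list(list(pid = "P2", condition = "SOT1", device = "equitest",
                       trial_index = 1, ei = 50))), f)
  expect_error(load_study(f), class = "sot_study_error")

  yaml::write_yaml(list(
    participants = list(list(pid = "P1", height = 1.7)),
    trials = list(list(pid = "P1", condition = "SOT1",
                       device = "equitest", trial_index = 1))), f)
  expect_error(load_study(f), class = "sot_manifest_error")

  yaml::write_yaml(list(), f)
  empty <- load_study(f)
  expect_s3_class(empty, "sot_study")
  expect_equal(nrow(empty$trials), 0)
  expect_equal(nrow(empty$participants), 0)
})
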