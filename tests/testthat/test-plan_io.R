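test_that("text plan dialect round-trips losslessly", {
  set.seed(17)
  plan <- generate_synthetic_plan(list(style = "tandem-ovoid"), seed = 23)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_plan_text(plan, f)
  back <- read_plan_text(f)

  expect_identical(back$plan_id, plan$plan_id)
  expect_identical(back$source_model_name, plan$source_model_name)
  expect_equal(back$calibration$Sk_calibration, plan$calibration$Sk_calibration,
               tolerance = 1e-12)
  expect_identical(back$calibration$calibration_date, plan$calibration$calibration_date)
  expect_identical(back$calibration$treatment_date, plan$calibration$treatment_date)
  expect_length(back$dwells, length(plan$dwells))
  for (i in seq_along(plan$dwells)) {
    expect_identical(back$dwells[[i]]$index, plan$dwells[[i]]$index)
    expect_identical(back$dwells[[i]]$channel, plan$dwells[[i]]$channel)
    expect_equal(back$dwells[[i]]$dwell_time_s, plan$dwells[[i]]$dwell_time_s,
                 tolerance = 1e-12)
    expect_equal(back$dwells[[i]]$geometry$center, plan$dwells[[i]]$geometry$center,
                 tolerance = 1e-12)
    expect_equal(back$dwells[[i]]$geometry$orientation,
                 plan$dwells[[i]]$geometry$orientation, tolerance = 1e-12)
  }
  for (i in seq_along(plan$points)) {
    expect_identical(back$points[[i]]$name, plan$points[[i]]$name)
    expect_identical(back$points[[i]]$dose_source, plan$points[[i]]$dose_source)
    expect_equal(back$points[[i]]$position, plan$points[[i]]$position,
                 tolerance = 1e-12)
    expect_equal(back$points[[i]]$tps_dose, plan$points[[i]]$tps_dose,
                 tolerance = 1e-12)
  }
})

test_that("text plan reader rejects schema violations, naming the field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  plan <- tiny_plan()
  write_plan_text(plan, f)
  doc <- yaml::read_yaml(f)
  doc$dwells[[1]]$time_s <- NULL
  yaml::write_yaml(doc, f)
  expect_error(read_plan_text(f), class = "brachycheck_format_error")
  expect_error(read_plan_text(f), "time_s")

  doc2 <- yaml::read_yaml(f)
  doc2$dwells[[1]]$time_s <- 12.5
  doc2$calibration$sk_U <- NULL
  yaml::write_yaml(doc2, f)
  expect_error(read_plan_text(f), "sk_U")

  expect_error(read_plan_text(file.path(tempdir(), "does-not-exist.yaml")),
               class = "brachycheck_format_error")
})

test_that("DICOM RT Plan channels flatten to dwells with recovered times", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_rtplan(f, list(straight_channel(n = 3, step_mm = 5, t_each = 10)))
  plan <- read_rtplan_dicom(f)
  expect_length(plan$dwells, 3)
  expect_equal(vapply(plan$dwells, `[[`, numeric(1), "dwell_time_s"),
               c(10, 10, 10), tolerance = 1e-9)
  expect_equal(plan$dwells[[2]]$geometry$center, c(0, 0, 0.5), tolerance = 1e-9)
  expect_equal(plan$dwells[[3]]$geometry$center, c(0, 0, 1.0), tolerance = 1e-9)
  # straight channel: every orientation is the channel tangent
  for (d in plan$dwells)
    expect_equal(d$geometry$orientation, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(plan$calibration$Sk_calibration, 40700, tolerance = 1e-9)
  expect_identical(plan$calibration$calibration_date, as.Date("2026-09-01"))
  expect_identical(plan$calibration$treatment_date, as.Date("2026-09-15"))
})

test_that("cumulative time weights recover dwell times by successive differences", {
  f <- withr::local_tempfile(fileext = ".dcm")
  ch <- list(number = 1, total_time = 100, final_weight = 1.0,
             cps = list(
               list(pos = c(0, 0, 0), weight = 0),
               list(pos = c(0, 0, 5), weight = 0.25),
               list(pos = c(0, 0, 5), weight = 0.25),
               list(pos = c(0, 0, 10), weight = 1.0)))
  write_test_rtplan(f, list(ch))
  plan <- read_rtplan_dicom(f)
  times <- vapply(plan$dwells, `[[`, numeric(1), "dwell_time_s")
  expect_equal(times, c(25, 0, 75), tolerance = 1e-9)
  # time conservation: recovered times sum to the channel total time
  expect_equal(sum(times), 100, tolerance = 1e-6)

  # zero final weight is rejected, naming the channel
  ch$final_weight <- 0
  write_test_rtplan(f, list(ch))
  expect_error(read_rtplan_dicom(f), class = "brachycheck_format_error")
  expect_error(read_rtplan_dicom(f), "channel 1")
})

test_that("non-RT-Plan DICOM files and non-DICOM files are refused", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_rtplan(f, list(straight_channel()),
                    sop_class = "1.2.840.10008.5.1.4.1.1.2")  # CT image storage
  expect_error(read_rtplan_dicom(f), class = "brachycheck_format_error")

  writeLines("not dicom", f)
  expect_error(read_rtplan_dicom(f), class = "brachycheck_format_error")
})

test_that("dose reference points become verification points with target doses", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_rtplan(f, list(straight_channel()),
                    points = list(
                      list(name = "point A left", pos_mm = c(-20, 0, 20), dose_gy = 6),
                      list(name = "bladder", pos_mm = c(0, 20, 10), dose_gy = 4.2)))
  plan <- read_rtplan_dicom(f)
  expect_length(plan$points, 2)
  expect_identical(plan$points[[1]]$name, "point A left")
  expect_equal(plan$points[[1]]$position, c(-2, 0, 2), tolerance = 1e-9)
  expect_equal(plan$points[[1]]$tps_dose, 600, tolerance = 1e-9)
  expect_identical(plan$points[[1]]$dose_source, "target")
})

test_that("DICOM and text readers agree on dwell geometry", {
  f_dcm <- withr::local_tempfile(fileext = ".dcm")
  # two channels, one with duplicated control-point positions
  write_test_rtplan(f_dcm, list(
    straight_channel(n = 4, step_mm = 5, t_each = 12, number = 1),
    list(number = 2, total_time = 60, final_weight = 3,
         cps = list(list(pos = c(15, 0, -5), weight = 0),
                    list(pos = c(15, 0, -5), weight = 1),
                    list(pos = c(17, 0, 0), weight = 2),
                    list(pos = c(19, 0, 5), weight = 3)))))
  plan <- read_rtplan_dicom(f_dcm)
  f_txt <- withr::local_tempfile(fileext = ".yaml")
  write_plan_text(plan, f_txt)
  back <- read_plan_text(f_txt)
  for (i in seq_along(plan$dwells)) {
    expect_equal(back$dwells[[i]]$geometry$center,
                 plan$dwells[[i]]$geometry$center, tolerance = 1e-9)
    expect_equal(back$dwells[[i]]$geometry$orientation,
                 plan$dwells[[i]]$geometry$orientation, tolerance = 1e-9)
  }
  # the tilted channel's orientations follow the polyline tangent
  ch2 <- Filter(function(d) d$channel == "2", plan$dwells)
  expect_length(ch2, 3)
  v <- c(2, 0, 5) / sqrt(29)
  expect_equal(ch2[[2]]$geometry$orientation, v, tolerance = 1e-9)
})

test_that("synthetic plan generation is deterministic and honors the applicator style", {
  p1 <- generate_synthetic_plan(seed = 1)
  p2 <- generate_synthetic_plan(seed = 1)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_plan_text(p1, f1); write_plan_text(p2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # straight tandem: collinear centers spaced by the step, axial orientations
  p <- generate_synthetic_plan(list(n_dwells = 5L, step_cm = 0.5), seed = 1)
  centers <- t(vapply(p$dwells, function(d) d$geometry$center, numeric(3)))
  expect_equal(centers[, 1], rep(0, 5))
  expect_equal(centers[, 2], rep(0, 5))
  expect_equal(diff(centers[, 3]), rep(0.5, 4), tolerance = 1e-12)
  for (d in p$dwells) expect_equal(d$geometry$orientation, c(0, 0, 1))
  expect_length(p$points, 4)

  ov <- generate_synthetic_plan(list(style = "tandem-ovoid"), seed = 2)
  expect_setequal(unique(vapply(ov$dwells, `[[`, character(1), "channel")),
                  c("tandem", "ovoid-left", "ovoid-right"))

  expect_error(generate_synthetic_plan(list(style = "ring"), seed = 1),
               class = "brachycheck_config_error")

  # the generator restores the caller's RNG state
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_synthetic_plan(seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("a tps_dose bias shifts the verification difference as 1/(1+bias) - 1", {
  plan <- generate_synthetic_plan(list(tps_bias = 0.02), seed = 6)
  run <- verify_plan(plan)
  for (res in run$results) {
    expect_equal(res$diff_percent, 100 * (1 / 1.02 - 1), tolerance = 1e-9)
    expect_false(res$passed)  # -1.96% is outside the 1.03% band
  }
})
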