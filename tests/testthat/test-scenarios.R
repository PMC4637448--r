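# Scenario plumbing (the heavy scenario physics is exercised in
# test-acceptance.R and shares its cached runs).

test_that("scenario presets encode the study conditions", {
  s <- scenario_spec("sheet2d")
  expect_equal(s$duration, 4000)
  expect_equal(s$dt, 0.01)
  s3 <- scenario_spec("pm3")
  expect_equal(s3$duration, 1200)
  expect_equal(s3$dt, 0.025)
  full <- scenario_spec("ridge", scale = "full")
  expect_equal(full$duration, 40000)
  expect_error(scenario_spec("wedge", duration = 10000), "desk scale")
  expect_error(run_scenario(scenario_spec("ridge", site = "bogus")),
               "unknown site")
})

test_that("drift-law report is empty for empty input and typed otherwise", {
  rep0 <- assert_drift_laws(list())
  expect_s3_class(rep0, "tbl_df")
  expect_equal(nrow(rep0), 0)
  expect_named(rep0, c("check", "passed", "detail"))
})

test_that("scenario artifacts are written to the run directory", {
  # reuses the wedge run cached by the acceptance tests (computed there
  # because test files run alphabetically)
  dir <- withr::local_tempdir()
  atriadrift:::write_scenario(drift_scenario("wedge"), dir)
  expect_true(file.exists(file.path(dir, "tips.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(s$scenario, "wedge")
  expect_true(is.numeric(s$thresholds$drift_threshold_mm))
})
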