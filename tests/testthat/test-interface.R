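test_that("full deformation records roundtrip through the CSV dialect", {
  rec <- analytic_record(n_frames = 9L, grid = seq(-4, 4, by = 0.25))
  d <- withr::local_tempdir()
  sp <- file.path(d, "spatial.csv"); tp <- file.path(d, "temporal.csv")
  write_deformation_record(rec, sp, tp)
  back <- read_deformation_record(sp, tp)
  expect_equal(back$times, rec$times, tolerance = 1e-12)
  expect_equal(back$heights, rec$heights, tolerance = 1e-12)
  expect_equal(back$apex_disp, rec$apex_disp, tolerance = 1e-12)
  expect_false(back$reduced)
})

test_that("reduced records support metrics but refuse per-frame access", {
  rec <- analytic_record(n_frames = 11L, grid = seq(-4, 4, by = 0.25))
  d <- withr::local_tempdir()
  sp <- file.path(d, "spatial.csv"); tp <- file.path(d, "temporal.csv")
  write_deformation_record(rec, sp, tp, reduced = TRUE)
  back <- read_deformation_record(sp, tp)
  expect_true(back$reduced)
  m_red <- compute_metrics(back)
  m_full <- compute_metrics(rec)
  expect_equal(m_red$DA, m_full$DA, tolerance = 1e-12)
  expect_equal(m_red$PDA, m_full$PDA, tolerance = 1e-12)
  hc <- which.max(back$apex_disp)
  expect_s3_class(record_frame(back, hc), "data.frame")
  expect_error(record_frame(back, 1L), "highest-concavity")
})

test_that("malformed record files raise parse errors with line numbers", {
  rec <- analytic_record(n_frames = 5L, grid = seq(-4, 4, by = 0.5))
  d <- withr::local_tempdir()
  sp <- file.path(d, "spatial.csv"); tp <- file.path(d, "temporal.csv")
  write_deformation_record(rec, sp, tp)

  # non-monotone time column
  tl <- readLines(tp)
  tl[c(3, 4)] <- tl[c(4, 3)]
  tp2 <- file.path(d, "bad_time.csv"); writeLines(tl, tp2)
  err <- tryCatch(read_deformation_record(sp, tp2), ap_parse_error = function(e) e)
  expect_s3_class(err, "ap_parse_error")
  expect_match(conditionMessage(err), "increasing")

  # ragged row
  sl <- readLines(sp)
  sl[4] <- paste0(sl[4], ",0.1")
  sp2 <- file.path(d, "ragged.csv"); writeLines(sl, sp2)
  err <- tryCatch(read_deformation_record(sp2, tp), ap_parse_error = function(e) e)
  expect_match(conditionMessage(err), ":4:")

  # wrong header
  sl <- readLines(sp); sl[1] <- "lateral,height"
  sp3 <- file.path(d, "hdr.csv"); writeLines(sl, sp3)
  expect_error(read_deformation_record(sp3, tp), class = "ap_parse_error")
})

test_that("stress-strain CSVs roundtrip", {
  curve <- simulate_tensile(mooney_rivlin(0.3, 0.1), tensile_spec(n_points = 21L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stress_strain(curve, path)
  back <- read_stress_strain(path)
  expect_equal(back$stress, curve$stress, tolerance = 1e-12)
})

test_that("configuration schema is validated and units converted", {
  expect_equal(mmhg_to_mpa(15), 15 * 133.322e-6)
  expect_equal(mpa_to_mmhg(mmhg_to_mpa(1)), 1)
  d <- withr::local_tempdir()
  good <- file.path(d, "good.yaml")
  yaml::write_yaml(list(geometry = list(thickness = 0.45),
                        material = list(c10 = 0.05, c01 = 0.02),
                        iop_mmhg = 15, seed = 3L), good)
  cfg <- read_run_config(good)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$geometry$anterior_radius, 9.05)
  expect_equal(cfg$material$c10, 0.05)

  bad <- file.path(d, "bad.yaml")
  yaml::write_yaml(list(geometry = list(thickness = 0.45), typo_key = 1), bad)
  expect_error(read_run_config(bad), class = "ap_config_error")

  nested <- file.path(d, "nested.yaml")
  yaml::write_yaml(list(solver = list(bogus = 1)), nested)
  expect_error(read_run_config(nested), class = "ap_config_error")

  incons <- file.path(d, "incons.yaml")
  yaml::write_yaml(list(geometry = list(posterior_radius = 8.6, thickness = 0.45,
                                        anterior_radius = 9.15)), incons)
  expect_error(read_run_config(incons), class = "ap_config_error")
})

test_that("CLI computes metrics, flags config errors and non-convergence", {
  d <- withr::local_tempdir()
  rec <- analytic_record(n_frames = 9L, grid = seq(-4, 4, by = 0.25))
  sp <- file.path(d, "spatial.csv"); tp <- file.path(d, "temporal.csv")
  write_deformation_record(rec, sp, tp)

  out <- file.path(d, "out")
  status <- ap_cli(c("metrics", "--spatial", sp, "--temporal", tp,
                     "--out", out, "--log-level", "quiet"))
  expect_identical(status, 0L)
  m <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_named(m, c("DA", "PDA", "CPR", "THC"))

  # usage / configuration errors exit with 2
  expect_identical(ap_cli(c("metrics", "--log-level", "quiet")), 2L)
  expect_identical(ap_cli(c("unknowncmd")), 2L)
  bad <- file.path(d, "bad.yaml")
  yaml::write_yaml(list(geometry = list(posterior_radius = 8.6, thickness = 0.45,
                                        anterior_radius = 9.15),
                        material = list(c10 = 0.05, c01 = 0.02)), bad)
  expect_identical(suppressMessages(
    ap_cli(c("simulate", "--config", bad, "--out", d, "--log-level", "quiet"))), 2L)

  # a hopeless load cannot converge: exit 3
  hopeless <- file.path(d, "hopeless.yaml")
  yaml::write_yaml(list(material = list(c10 = 0.002, c01 = 0.001),
                        airpuff = list(peak_pressure_mpa = 0.5, n_frames = 3L),
                        solver = list(n_through_thickness = 2L, n_meridian = 20L,
                                      n_holder = 3L, n_increments = 2L)), hopeless)
  expect_identical(suppressMessages(
    ap_cli(c("simulate", "--config", hopeless, "--out", d,
             "--log-level", "quiet"))), 3L)
})

test_that("CLI tensile and synth subcommands write their artifacts", {
  d <- withr::local_tempdir()
  cfgp <- file.path(d, "cfg.yaml")
  yaml::write_yaml(list(material = list(c10 = 0.0375, c01 = 0.0125),
                        tensile = list(n_points = 21L),
                        airpuff = list(n_frames = 5L),
                        solver = list(n_through_thickness = 2L, n_meridian = 24L,
                                      n_holder = 4L),
                        seed = 11L), cfgp)
  out <- file.path(d, "t")
  expect_identical(ap_cli(c("tensile", "--config", cfgp, "--out", out,
                            "--log-level", "quiet")), 0L)
  tr <- jsonlite::read_json(file.path(out, "tensile_result.json"))
  expect_equal(tr$equivalent_modulus_mpa,
               equivalent_youngs_modulus(
                 simulate_tensile(mooney_rivlin(0.0375, 0.0125),
                                  tensile_spec(n_points = 21L))),
               tolerance = 1e-9)
  out2 <- file.path(d, "s")
  expect_identical(ap_cli(c("synth", "--config", cfgp, "--out", out2,
                            "--log-level", "quiet")), 0L)
  expect_true(file.exists(file.path(out2, "spatial_profiles.csv")))
  expect_true(file.exists(file.path(out2, "ground_truth.json")))
})
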