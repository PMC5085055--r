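test_that("deformation parameters match their definitions on a synthetic record", {
  rec <- analytic_record(da = 1.2, d2mm = 0.8)
  m <- compute_metrics(rec)
  expect_equal(m$DA, 1.2, tolerance = 1e-3)
  expect_equal(m$PDA, 0.8, tolerance = 1e-3)
  expect_equal(m$CPR, 1.5, tolerance = 2e-3)
  expect_equal(m$THC, 15, tolerance = 0.2)
})

test_that("a trace peaking at frame 70 of 140 over 30 ms gives THC of 15 ms", {
  rec <- analytic_record(peak_frame = 70L)
  expect_equal(compute_metrics(rec)$THC, 30 * 69 / 139, tolerance = 0.15)
  expect_equal(compute_metrics(rec)$THC, 15, tolerance = 0.3)
})

test_that("rigid translation of the surface gives CPR of 1", {
  grid <- seq(-4, 4, by = 0.05)
  times <- seq(0, 30, length.out = 11)
  shape <- 1 - ((times - 15) / 15)^2 # exactly quadratic bell
  ref <- 10 - grid^2 / 18
  d <- 0.7
  heights <- t(vapply(shape, function(s) ref - s * d, numeric(length(grid))))
  rec <- airpuffr:::new_deformation_record(times, grid, heights, ref,
                                           apex_disp = shape * d)
  expect_equal(compute_metrics(rec)$CPR, 1, tolerance = 1e-9)
})

test_that("metrics are invariant to lateral mirroring of the record", {
  rec <- analytic_record()
  # break the exact symmetry slightly so the mirror test is non-trivial
  set.seed(5)
  rec$heights <- rec$heights + matrix(stats::rnorm(length(rec$heights), 0, 1e-4),
                                      nrow(rec$heights))
  rec$reference <- rec$heights[1, ]
  mir <- rec
  mir$grid <- rev(-rec$grid)
  mir$heights <- rec$heights[, rev(seq_along(rec$grid))]
  mir$reference <- rev(rec$reference)
  m1 <- compute_metrics(rec)
  m2 <- compute_metrics(mir)
  expect_equal(m1$DA, m2$DA, tolerance = 1e-12)
  expect_equal(m1$PDA, m2$PDA, tolerance = 1e-12)
})

test_that("merit aggregates DA and CPR residuals with the 1/3 weight", {
  m1 <- structure(list(DA = 1.0, PDA = 0.5, CPR = 2.0, THC = 15),
                  class = "deformation_metrics")
  m2 <- structure(list(DA = 0.9, PDA = 0.53, CPR = 1.7, THC = 15),
                  class = "deformation_metrics")
  expect_equal(merit(m1, m1), 0)
  expect_equal(merit(m1, m2), 0.1 + 0.1, tolerance = 1e-12)
  expect_equal(merit(m1, m2), merit(m2, m1))
  expect_equal(merit(m1, m2, weight_cpr = 1), 0.4, tolerance = 1e-12)
})

test_that("profile RMS matches closed forms and obeys the triangle inequality", {
  x <- seq(-4, 4, by = 0.1)
  a <- cbind(x, 0.5 * x)
  expect_equal(profile_rms(a, a), 0)
  b <- cbind(x, 0.5 * x + 0.05)
  expect_equal(profile_rms(a, b), 0.05, tolerance = 1e-12)
  # two ramps differing in slope by 0.02 over +/-4 mm
  c_ <- cbind(x, 0.52 * x)
  # the shared grid is discrete, so allow the O(1/n) quadrature deviation
  expect_equal(profile_rms(a, c_), 0.02 * sqrt(16 / 3), tolerance = 0.01)
  expect_equal(profile_rms(a, c_), 0.0462, tolerance = 0.01)
  set.seed(9)
  for (i in 1:20) {
    ya <- cbind(x, stats::rnorm(length(x)))
    yb <- cbind(x, stats::rnorm(length(x)))
    yc <- cbind(x, stats::rnorm(length(x)))
    expect_lte(profile_rms(ya, yc),
               profile_rms(ya, yb) + profile_rms(yb, yc) + 1e-12)
  }
  expect_error(profile_rms(cbind(0:1, 0:1), cbind(5:6, 0:1)), "overlap")
})

test_that("point-to-point correspondence matches hand-computed values", {
  eps <- seq(0, 0.4, by = 0.01)
  ref <- cbind(eps, 2 * eps + 5 * eps^2)
  expect_equal(correspondence(ref, ref), 100)
  test <- cbind(eps, 1.10 * (2 * eps + 5 * eps^2))
  expect_equal(correspondence(ref, test, strain_range = c(0.1, 0.4)), 90,
               tolerance = 1e-9)
  # linear reference sigma = eps, test shifted by 0.01, 4-point grid
  lin_ref <- cbind(eps, eps)
  lin_test <- cbind(eps, eps + 0.01)
  got <- correspondence(lin_ref, lin_test, strain_range = c(0.1, 0.4),
                        n_grid = 4L)
  expect_equal(got, 100 * (1 - mean(0.01 / c(0.1, 0.2, 0.3, 0.4))),
               tolerance = 1e-9)
  expect_equal(got, 94.79167, tolerance = 1e-4)
  expect_error(correspondence(lin_ref, lin_test, strain_range = c(0, 0.5)),
               "cover")
})
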