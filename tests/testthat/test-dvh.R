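test_that("compute_dvh handles uniform dose and reports exact volume", {
  vals <- array(50, dim = c(4, 4, 4))
  g <- dose_grid(vals, c(1, 1, 1), rbe_model = "LEM")
  m <- structure_mask(array(TRUE, dim = c(4, 4, 4)), "rectum")
  dvh <- compute_dvh(g, m)
  expect_s3_class(dvh, "dvh")
  expect_identical(dvh$rbe_model, "LEM")
  expect_equal(dvh$total_volume_cc, 64 / 1000)
  # fraction 1 up to 50, 0 above
  below <- dvh$dose_edges <= 50
  expect_true(all(dvh$cum_volume_fraction[below] == 1))
  expect_true(all(dvh$cum_volume_fraction[!below] == 0))
  expect_equal(dose_at_volume(dvh, "percent", 5), 50, tolerance = 0.1)

  # 2x2x2 mask of 1 mm voxels -> 0.008 cc
  sub <- array(FALSE, dim = c(4, 4, 4)); sub[1:2, 1:2, 1:2] <- TRUE
  expect_equal(compute_dvh(g, structure_mask(sub))$total_volume_cc, 0.008)
})

test_that("compute_dvh validates inputs", {
  g <- dose_grid(array(1, dim = c(2, 2, 2)), c(1, 1, 1))
  expect_error(compute_dvh(g, structure_mask(array(FALSE, dim = c(2, 2, 2)))),
               "empty structure")
  expect_error(compute_dvh(g, structure_mask(array(TRUE, dim = c(3, 2, 2)))),
               "shape")
  expect_error(compute_dvh(g, structure_mask(array(TRUE, dim = c(2, 2, 2))),
                           bin_width = 0), "bin_width")
  expect_error(dose_grid(array(-1, dim = c(2, 2, 2)), c(1, 1, 1)), ">= 0")
  expect_error(dose_grid(array(1, dim = c(2, 2, 2)), c(1, 0, 1)), "positive")
})

test_that("binned DVH matches the sort-based oracle within one bin width", {
  set.seed(101)
  for (rep in 1:5) {
    rg <- make_random_grid(dim = c(20, 20, 20))
    dvh <- compute_dvh(rg$grid, rg$mask, bin_width = 0.1)
    for (v in c(1, 5, 10, 20, 50, 90)) {
      err <- abs(dose_at_volume(dvh, "percent", v) -
                   oracle_dose_at_fraction(rg$doses, v / 100))
      expect_lt(err, 0.1 + 1e-9, label = sprintf("D_%d%% error, rep %d", v, rep))
    }
    # survival values at the bin edges are exact by construction
    idx <- sample(seq_along(dvh$dose_edges), 25)
    expect_equal(dvh$cum_volume_fraction[idx],
                 vapply(dvh$dose_edges[idx],
                        function(d) mean(rg$doses >= d), numeric(1)),
                 tolerance = 1e-12)
  }
  # one larger grid exercising the re-binning path
  rg <- make_random_grid(dim = c(50, 50, 50))
  dvh <- compute_dvh(rg$grid, rg$mask, bin_width = 0.1)
  expect_lt(abs(dose_at_volume(dvh, "percent", 2) -
                  oracle_dose_at_fraction(rg$doses, 0.02)), 0.1 + 1e-9)
})

test_that("dose_at_volume interpolates and converts cc specs", {
  lin <- make_linear_dvh(100, volume_cc = 80)
  expect_equal(dose_at_volume(lin, "percent", 20), 80)
  expect_equal(dose_at_volume(lin, "cc", 4), dose_at_volume(lin, "percent", 5))
  expect_error(dose_at_volume(lin, "percent", 0), "> 0")
  expect_error(dose_at_volume(lin, "percent", 101), "100")
  expect_error(dose_at_volume(lin, "cc", 81), "exceeds")
})

test_that("volume_at_dose inverts the curve and handles extremes", {
  uni <- make_uniform_dvh(50)
  expect_equal(volume_at_dose(uni, 49), 1)
  expect_equal(volume_at_dose(uni, 51), 0)
  lin <- make_linear_dvh(100)
  expect_equal(volume_at_dose(lin, 30), 0.70)
  expect_error(volume_at_dose(lin, -1), ">= 0")
  # round trip on a strictly decreasing segment
  for (d in c(12.3, 47.9, 88.2)) {
    expect_equal(dose_at_volume(lin, "percent", 100 * volume_at_dose(lin, d)),
                 d, tolerance = 1e-9)
  }
})

test_that("gEUD limits: uniform identity, mean at n = 1, max as n -> 0", {
  uni <- make_uniform_dvh(60)
  for (n in c(0.035, 0.5, 1, 5)) expect_equal(geud(uni, n), 60,
                                              tolerance = 1e-6)
  expect_equal(geud(make_two_bin_dvh(40, 60), n = 1), 50, tolerance = 1e-6)
  # independent power-sum oracle at the serial-organ default
  expect_equal(geud(make_two_bin_dvh(30, 60), n = 0.035),
               (0.5 * 30^(1 / 0.035) + 0.5 * 60^(1 / 0.035))^0.035,
               tolerance = 1e-6)
  # n -> 0+ approaches the maximum dose without overflow
  tb <- make_two_bin_dvh(30, 60)
  expect_lt(abs(geud(tb, n = 1e-4) - 60) / 60, 0.005)
  expect_error(geud(tb, n = 0), "> 0")
  expect_error(geud(tb, n = -1), "> 0")
})

test_that("gEUD is monotone in every dose bin", {
  lo <- make_two_bin_dvh(30, 60)
  hi_cold <- make_two_bin_dvh(35, 60)
  hi_hot <- make_two_bin_dvh(30, 65)
  for (n in c(0.035, 1)) {
    expect_gt(geud(hi_cold, n), geud(lo, n))
    expect_gt(geud(hi_hot, n), geud(lo, n))
  }
})

test_that("D_v is monotone non-increasing in v", {
  set.seed(7)
  rg <- make_random_grid(dim = c(15, 15, 15))
  dvh <- compute_dvh(rg$grid, rg$mask)
  dv <- vapply(c(1, 5, 10, 20), function(v)
    dose_at_volume(dvh, "percent", v), numeric(1))
  expect_true(all(diff(dv) <= 0))
})

test_that("average_dvh returns per-bin mean and population SD", {
  lin <- make_linear_dvh(100)
  avg <- average_dvh(list(lin, lin))
  expect_equal(max(avg$sd), 0)
  expect_equal(stats::approx(avg$dose_edges, avg$mean, 30)$y, 0.7,
               tolerance = 1e-9)
  # two-point statistics: fractions {1, 0} and {1, 1} at an interior bin
  a <- new_dvh(c(0, 10, 10.1), c(1, 1, 0), 50)
  b <- new_dvh(c(0, 20, 20.1), c(1, 1, 0), 50)
  avg2 <- average_dvh(list(a, b), bin_width = 5)
  at15 <- which(avg2$dose_edges == 15)
  expect_equal(avg2$mean[at15], 0.5)
  expect_equal(avg2$sd[at15], 0.5)
  expect_true(all(diff(avg2$mean) <= 1e-12))
  expect_error(average_dvh(list(lin)), "at least 2")
  # brute-force oracle on a generated batch
  coh <- generate_cohort(cohort_config(group_sizes = c(prostate = 10L)),
                         seed = 3)
  dvhs <- lapply(coh$patients, `[[`, "dvh_lem")
  avg3 <- average_dvh(dvhs)
  mat <- vapply(dvhs, volume_at_dose, numeric(length(avg3$dose_edges)),
                dose = avg3$dose_edges)
  expect_equal(avg3$mean, rowMeans(mat), tolerance = 1e-12)
  expect_equal(avg3$sd, apply(mat, 1, function(r) sqrt(mean((r - mean(r))^2))),
               tolerance = 1e-12)
})

test_that("new_dvh enforces its invariants", {
  expect_error(new_dvh(c(0, 1), c(0.9, 0), 10), "start at 1")
  expect_error(new_dvh(c(0, 1), c(1, 0.1), 10), "end at 0")
  expect_error(new_dvh(c(0, 1, 1), c(1, 0.5, 0), 10), "strictly increasing")
  expect_error(new_dvh(c(0, 1, 2), c(1, 0.2, 0.5, 0), 10), "equal length")
  expect_error(new_dvh(c(0, 1, 2), c(1, 1.2, 0), 10), NULL)
  expect_error(new_dvh(c(0, 1), c(1, 0), 0), "> 0")
})
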