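test_that("built-in constraint sets carry the clinical limits", {
  sets <- builtin_constraint_set()
  expect_named(sets, c("OLD_MKM", "SACRUM_PRV", "TRANSLATED_LEM", "NEW_CC"))
  old <- builtin_constraint_set("OLD_MKM")
  lims <- vapply(old$constraints, `[[`, 0, "limit")
  expect_equal(lims, c(28.8, 46.4, 60, 66))
  expect_equal(vapply(old$constraints, `[[`, "", "priority"),
               c("soft", "soft", "hard", "hard"))
  ncc <- builtin_constraint_set("NEW_CC")
  expect_equal(vapply(ncc$constraints, `[[`, "", "kind"), rep("cc", 3))
  expect_equal(vapply(ncc$constraints, `[[`, 0, "limit"), c(66, 61, 54))
  expect_error(builtin_constraint_set("NOPE"), "unknown constraint set")
  expect_error(constraint_set("dup", list(
    dose_constraint("percent", 5, 60, "MKM"),
    dose_constraint("percent", 5, 50, "MKM"))), "duplicate")
})

test_that("evaluate_constraints reports observed doses and enforces language", {
  uni <- make_uniform_dvh(50, rbe_model = "MKM")
  rep1 <- evaluate_constraints(uni, builtin_constraint_set("OLD_MKM"))
  expect_equal(nrow(rep1), 4)
  expect_true(all(abs(rep1$observed - 50) <= 0.1))
  expect_equal(rep1$pass, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(
    evaluate_constraints(make_uniform_dvh(50, rbe_model = "LEM"),
                         builtin_constraint_set("OLD_MKM")),
    "RBE-language mismatch")
})

test_that("boundary equality counts as compliant", {
  cs <- constraint_set("edge", list(dose_constraint("percent", 50, 50, "MKM")))
  lin <- make_linear_dvh(100, rbe_model = "MKM")  # D_50% = 50 exactly
  expect_true(evaluate_constraints(lin, cs)$pass)
  # just over the tolerance fails
  cs2 <- constraint_set("edge2",
                        list(dose_constraint("percent", 50, 49.9, "MKM")))
  expect_false(evaluate_constraints(lin, cs2)$pass)
})

test_that("limits below the minimum dose always fail, above the maximum always pass", {
  set.seed(17)
  rg <- make_random_grid(dim = c(10, 10, 10), dmax = 60)
  dvh <- compute_dvh(rg$grid, rg$mask)
  low <- constraint_set("low", list(dose_constraint("percent", 50, 1e-3, "MKM")))
  high <- constraint_set("high", list(dose_constraint("percent", 50, 200, "MKM")))
  expect_false(evaluate_constraints(dvh, low)$pass)
  expect_true(evaluate_constraints(dvh, high)$pass)
  # hard/soft never alters pass/fail
  soft <- constraint_set("soft", list(
    dose_constraint("percent", 50, 1e-3, "MKM", priority = "soft")))
  expect_equal(evaluate_constraints(dvh, soft)$pass,
               evaluate_constraints(dvh, low)$pass)
})

test_that("published re-optimized plans respect the nominal mMKM limits", {
  plans <- reoptimized_plans()
  expect_equal(nrow(plans), 5)
  old <- builtin_constraint_set("OLD_MKM")
  reports <- do.call(rbind, lapply(seq_len(nrow(plans)), function(i) {
    metrics <- data.frame(kind = "percent", amount = c(20, 10, 5, 1),
                          observed = as.numeric(plans[i, c("d_mkm_20",
                                                           "d_mkm_10",
                                                           "d_mkm_5",
                                                           "d_mkm_1")]))
    evaluate_metric_table(metrics, old, "MKM",
                          patient_id = plans$patient_id[i])
  }))
  hard <- reports[reports$constraint %in% c("D_5%", "D_1%"), ]
  expect_true(all(hard$pass))
  fails <- reports[!reports$pass, ]
  # failures only on the soft D_20%/D_10% limits, only for sacral plans
  expect_true(all(fails$constraint %in% c("D_20%", "D_10%")))
  expect_true(all(grepl("sac", fails$patient_id)))
  # the high-dose sacral plan exceeds the soft D_20% limit of 28.8
  h1 <- reports[reports$patient_id == "h_sac_1" &
                  reports$constraint == "D_20%", ]
  expect_false(h1$pass)
  expect_equal(h1$observed, 37.0)
})

test_that("cohort_compliance reports exceedance fractions to 0.1%", {
  mk_row <- function(pass, id) data.frame(
    patient_id = id, constraint_set = "OLD_MKM", constraint = "D_10%",
    kind = "percent", amount = 10, rbe_model = "MKM", priority = "soft",
    limit = 46.4, observed = 40, margin = 6.4, pass = pass,
    stringsAsFactors = FALSE)
  reports <- do.call(rbind, lapply(1:63, function(i)
    mk_row(i != 1, sprintf("p%02d", i))))
  cc <- cohort_compliance(reports)
  expect_equal(cc$n_fail, 1)
  expect_equal(cc$exceedance_pct, 1.6)
  # 27 of 63 and zero of 63
  reports$pass <- rep(c(FALSE, TRUE), c(27, 36))
  expect_equal(cohort_compliance(reports)$exceedance_pct, 42.9)
  reports$pass <- TRUE
  expect_equal(cohort_compliance(reports)$exceedance_pct, 0)
  expect_error(cohort_compliance(reports[0, ]), "non-empty")
})

test_that("expand_mask performs isotropic spherical dilation", {
  m <- array(FALSE, dim = c(9, 9, 9)); m[5, 5, 5] <- TRUE
  prv <- expand_mask(structure_mask(m, "rectum"), c(2, 2, 2), margin_mm = 5)
  expect_identical(prv$name, "rectum_prv")
  # independent oracle: voxels whose centre lies within 5 mm
  expected <- array(FALSE, dim = c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    if (sum(((c(i, j, k) - 5) * 2)^2) <= 25) expected[i, j, k] <- TRUE
  }
  expect_identical(prv$mask, expected)
  # dilation is monotone: the original mask is contained
  expect_true(all(prv$mask[m]))
  # zero margin is the identity
  expect_identical(expand_mask(structure_mask(m), c(2, 2, 2), 0)$mask, m)
})
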