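# Internal-standard assignment, normalization, and differential testing.

test_that("internal standards are assigned by name, class, then RT", {
  isl <- is_library(ba_library())
  expect_equal(assign_internal_standard("GCA", "glycine", 12.6, isl),
               "d4-GCA")
  # an unconjugated isomer at 25.3 min takes the nearest unconjugated IS
  expect_equal(assign_internal_standard("CDCA isomer", "unconjugated",
                                        25.3, isl), "d4-CDCA")
  # empty class subset falls back to the globally nearest RT
  no_tau <- isl[isl$conjugation_class != "taurine", ]
  expect_equal(assign_internal_standard("THCA", "taurine", 6.6, no_tau),
               "d4-GUDCA")  # nearest-RT fallback across all classes
  expect_equal(assign_internal_standard("THCA", "taurine", 6.6, no_tau),
               assign_internal_standard("THCA", NA, 6.6, no_tau))
  expect_error(assign_internal_standard("X", NA, 1, isl[0, ]), "empty")
})

test_that("area ratios are analyte over IS, flagged when IS is missing", {
  areas <- data.frame(sample_id = c("a", "b"), area = c(2000, 1500))
  is_areas <- data.frame(sample_id = "a", area = 1000)
  r <- normalize_areas(areas, is_areas)
  expect_equal(r$ratio, c(2.0, NA))
  expect_equal(r$flag, c(NA, "is_missing"))
})

test_that("IS normalization cancels per-sample intensity drift", {
  cfg <- default_scenario(23)
  cfg$sample_scale <- rep(c(1, 1, 1, 1.5), each = 3)  # drift on the top dose
  study <- make_plasma_study(cfg)
  truth <- study$truth
  f <- study$features
  grp <- study$design$group[match(f$sample_id, study$design$sample_id)]
  dca <- truth$label == "DCA"
  isd <- truth$label == "d4-DCA"
  raw_fc <- mean(f$area[dca & grp == "600"]) / mean(f$area[dca & grp == "75"])
  ratio <- f$area[dca] / f$area[isd][match(f$sample_id[dca], f$sample_id[isd])]
  g2 <- grp[dca]
  norm_fc <- mean(ratio[g2 == "600"]) / mean(ratio[g2 == "75"])
  expect_gt(raw_fc, 7.5)                     # drift inflates the raw contrast
  expect_equal(norm_fc, 6.0, tolerance = 0.2)      # ratios recover the truth
})

test_that("the t-test handles plain, degenerate, and mirrored inputs", {
  r <- differential_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  expect_equal(r$fold_change, 1)
  expect_false(r$significant)
  # frozen example: threefold replicates around 1 vs around 6
  lo <- c(1.0, 1.1, 0.9); hi <- c(6.0, 6.6, 5.4)
  r <- differential_test(lo, hi)
  expect_equal(r$fold_change, 6.0, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_student_p(hi, lo), tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
  # swapping the groups inverts the fold change, p unchanged
  rs <- differential_test(hi, lo)
  expect_equal(rs$fold_change, 1 / r$fold_change, tolerance = 1e-12)
  expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
  expect_false(rs$significant)               # a decrease, not an increase
  expect_true(differential_test(hi, lo, two_sided_fc = TRUE)$significant)
  # constant equal groups: p = 1; zero low mean: fold change undefined
  expect_equal(differential_test(c(2, 2), c(2, 2))$p_value, 1)
  z <- differential_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(z$flag, "fc_undefined")
  expect_true(is.na(z$fold_change))
  expect_error(differential_test(1, c(1, 2)), "at least 2")
})

test_that("p-values agree with the t-distribution oracle to 1e-9", {
  set.seed(101)
  for (i in 1:100) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rlnorm(nx, 0, 0.2); y <- rlnorm(ny, 0.5, 0.3)
    expect_equal(differential_test(x, y)$p_value, oracle_student_p(y, x),
                 tolerance = 1e-9)
  }
})

test_that("printed reference tables re-screen to the reported counts", {
  expect_equal(sum(isomer_reference()$p_value < 0.01), 5)
  t2 <- sulfate_reference()
  res <- data.frame(tier = "conjugate_tentative", delta_name = "sulfation",
                    p_value = t2$p_value, fold_change = t2$fold_change)
  counts <- summarize_profile(res)
  expect_equal(unname(counts["sulfate"]), 9L)
  expect_equal(unname(counts["identified"]), 0L)
  expect_equal(summarize_profile(data.frame()),
               c(identified = 0L, isomer = 0L, sulfate = 0L,
                 glucuronide = 0L))
})

test_that("the screen's type-I error is controlled at the nominal level", {
  p <- simulate_null_pvalues(400, n_per_group = 3, cv = 0.10, seed = 11)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
  expect_true(all(p >= 0 & p <= 1))
})
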