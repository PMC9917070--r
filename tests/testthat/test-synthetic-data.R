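# The synthetic-study generator: reproducibility, noise model, planted truth.

test_that("identical configurations reproduce byte-identical studies", {
  a <- make_plasma_study(default_scenario(99))
  b <- make_plasma_study(default_scenario(99))
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  c <- make_plasma_study(default_scenario(100))
  expect_false(identical(a$features, c$features))
  iva <- make_invitro_suite(default_scenario(99))
  ivb <- make_invitro_suite(default_scenario(99))
  expect_identical(iva$runs, ivb$runs)
})

test_that("the noiseless limit reproduces plantings exactly", {
  cfg <- default_scenario(1)
  cfg$analytical_cv <- 0
  cfg$mass_error_ppm_sd <- 0
  cfg$rt_jitter_sd <- 0
  study <- make_plasma_study(cfg)
  f <- study$features
  truth <- study$truth
  lib <- ba_library()
  grp <- study$design$group[match(f$sample_id, study$design$sample_id)]
  dca <- truth$label == "DCA"
  # areas exactly baseline x geometric dose multiplier
  expect_equal(unique(f$area[dca & grp == "75"]), cfg$baseline_area)
  expect_equal(unique(f$area[dca & grp == "600"]), cfg$baseline_area * 6.0)
  expect_equal(unique(f$area[dca & grp == "150"]),
               cfg$baseline_area * 6.0^(1 / 3), tolerance = 1e-12)
  # masses exactly theoretical
  expect_equal(unique(f$mz[dca]), lib$mz[lib$name == "DCA"], tolerance = 1e-10)
  expect_equal(unique(f$rt_min[dca]), lib$reference_rt_min[lib$name == "DCA"])
})

test_that("every planted feature respects the configured error truncation", {
  study <- default_study()
  cfg <- study$config
  expect_true(all(abs(study$truth$ppm_error_true) <= cfg$mass_error_ppm_max))
  expect_true(all(abs(study$truth$rt_jitter_true) <= cfg$rt_jitter_max))
  # observed m/z is consistent with theoretical x (1 + eps)
  planted <- !is.na(study$truth$formula)
  lib <- ba_library()
  isl <- is_library(lib)
  theo <- ifelse(study$truth$label %in% isl$name,
                 isl$mz[match(study$truth$label, isl$name)],
                 vapply(study$truth$formula, function(fm) {
                   if (is.na(fm)) NA_real_ else mz_mh_minus(fm)
                 }, numeric(1)))
  back_ppm <- (study$features$mz / theo - 1) * 1e6
  expect_equal(back_ppm[planted], study$truth$ppm_error_true[planted],
               tolerance = 1e-6)
})

test_that("the default study has the configured feature complement", {
  study <- default_study()
  cfg <- study$config
  per_sample <- table(study$features$sample_id)
  n_expected <- 46 + 14 + nrow(cfg$isomers) + nrow(cfg$sulfates) +
    nrow(cfg$extra_sulfates) + nrow(cfg$glucuronides) +
    nrow(cfg$misassigned) + cfg$n_decoys
  expect_equal(length(per_sample), 12)
  expect_true(all(per_sample == n_expected))
  # every non-decoy feature has exactly one truth record with a formula
  expect_equal(nrow(study$truth), nrow(study$features))
  expect_false(anyDuplicated(study$truth$feature_id) > 0)
  expect_true(all(!is.na(study$truth$formula[study$truth$kind != "decoy"])))
})

test_that("planted spectra classify to their planted conjugate class", {
  study <- default_study()
  cls <- classify_spectra(study$spectra)
  truth_class <- vapply(study$spectra, function(s) {
    unique(study$truth$true_class[study$truth$label == s$key])
  }, character(1))
  expect_identical(unname(cls$msms_class[match(names(study$spectra),
                                               cls$key)]),
                   unname(truth_class))
  expect_true(any(truth_class == "taurine"))
  expect_true(any(truth_class == "sulfate"))
  expect_true(any(truth_class == "glycine"))
})

test_that("control runs lack the blocked cofactor's metabolites", {
  cfg <- default_scenario(5)
  cfg$invitro$leakage <- 0
  iv <- make_invitro_suite(cfg)
  lca <- iv$runs[["LCA"]]
  plan <- iv$truth[iv$truth$parent == "LCA", ]
  sulf_mz <- plan$mz_theo[plan$delta_name == "sulfation"]
  ox_mz <- plan$mz_theo[plan$delta_name != "sulfation"]
  near <- function(feats, mzs) {
    any(vapply(mzs, function(m) any(abs(ppm_error(feats$mz, m)) < 20),
               logical(1)))
  }
  expect_false(near(lca$controls$no_PAPS, sulf_mz))   # sulfation blocked
  expect_false(near(lca$controls$no_NADP, ox_mz))     # oxidation blocked
  expect_true(near(lca$full, sulf_mz) && near(lca$full, ox_mz))
  bad <- cfg
  bad$invitro$plan <- data.frame(parent = "XYZ",
                                 delta_name = "hydroxylation", rt_min = 5)
  expect_error(make_invitro_suite(bad), "unknown incubation parent")
})
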