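# Diagnostic-ion classification and annotation reconciliation.

test_that("diagnostic masses derive from formulas and round as printed", {
  ions <- diagnostic_ions()
  mz_of <- function(ion) ions$mz[ions$ion == ion]
  expect_equal(round(mz_of("glycine [M-H]-"), 2), 74.02)
  expect_equal(round(mz_of("taurine [M-H]-"), 2), 124.01)
  expect_equal(round(mz_of("HSO4-"), 2), 96.96)
  expect_equal(round(mz_of("C2H3SO3-"), 2), 106.98)
  expect_equal(round(mz_of("SO3-."), 2), 79.96)
  # HSO3- computes to 80.9652 (displays as 80.97); the computed value rules
  expect_equal(mz_of("HSO3-"), 80.9652, tolerance = 1e-4)
})

test_that("classification follows presence rules and precedence", {
  ions <- diagnostic_ions()
  mz_of <- function(ion) ions$mz[ions$ion == ion]
  expect_equal(classify_spectrum(ba_spectrum("e", 500, numeric(0), numeric(0))),
               "none")
  # sulfate outranks glycine
  s <- ba_spectrum("s1", 500, c(96.960, 74.025), c(50, 30))
  expect_equal(classify_spectrum(s), "sulfate")
  # the taurine primary ion alone suffices and outranks sulfate
  s <- ba_spectrum("s2", 500, c(124.007, 96.960), c(20, 50))
  expect_equal(classify_spectrum(s), "taurine")
  # two taurine companions suffice without the primary ion
  s <- ba_spectrum("s3", 500, c(mz_of("HSO3-"), mz_of("SO3-.")), c(10, 5))
  expect_equal(classify_spectrum(s), "taurine")
  # one companion alone is ambiguous -> not taurine
  s <- ba_spectrum("s4", 500, mz_of("SO3-."), 10)
  expect_equal(classify_spectrum(s), "none")
  # glycine when only its ion is present
  s <- ba_spectrum("s5", 500, 74.0248, 60)
  expect_equal(classify_spectrum(s), "glycine")
})

test_that("classification ignores peak order and sub-threshold peaks", {
  mzs <- c(96.9601, 350.1, 200.2, 74.0248)
  ints <- c(40, 5, 3, 30)
  ord <- sample(4)
  expect_equal(classify_spectrum(ba_spectrum("a", 500, mzs[ord], ints[ord])),
               "sulfate")
  # the sulfate ion below the relative-intensity threshold no longer counts
  weak <- ba_spectrum("b", 500, c(96.9601, 74.0248), c(0.5, 30))
  expect_equal(classify_spectrum(weak), "glycine")
  expect_equal(classify_spectrum(weak, min_rel_intensity = 0.1), "sulfate")
})

test_that("contradicting MS/MS reclassifies isomeric formulas", {
  lib <- ba_library()
  targets <- build_target_list(lib)
  # a feature at the GLCA+SO3 exact mass whose spectrum is taurine-type
  f <- data.frame(sample_id = "S1", feature_id = "x1",
                  mz = mz_mh_minus("C26H43NO7S"), rt_min = 10.9, area = 1e5)
  a <- annotate_features(f, targets)
  expect_equal(a$tier, "conjugate_tentative")
  expect_equal(a$target_name, "GLCA+SO3")
  rec <- reconcile_annotation(a, "taurine", lib)
  expect_equal(rec$msms_flag, "msms_reassigned")
  expect_equal(rec$target_name, "taurine conjugate of keto-DCA isomer")
  # agreement leaves the annotation unchanged
  f2 <- data.frame(sample_id = "S1", feature_id = "x2",
                   mz = mz_mh_minus("C24H40O7S"), rt_min = 21.6, area = 1e5)
  a2 <- annotate_features(f2, targets)
  rec2 <- reconcile_annotation(a2, "sulfate", lib)
  expect_true(is.na(rec2$msms_flag))
  expect_equal(rec2$target_name, a2$target_name)
  # an uninformative spectrum changes nothing
  rec3 <- reconcile_annotation(a2, "none", lib)
  expect_true(is.na(rec3$msms_flag))
  # no isomeric reinterpretation exists: unconjugated isomer + glycine call
  f4 <- data.frame(sample_id = "S1", feature_id = "x4",
                   mz = mz_mh_minus("C24H40O4"), rt_min = 25.3, area = 1e5)
  a4 <- annotate_features(f4, targets)
  expect_equal(a4$tier, "isomer")
  rec4 <- reconcile_annotation(a4, "glycine", lib)
  expect_equal(rec4$msms_flag, "msms_conflict")
  expect_equal(rec4$target_name, a4$target_name)
})

test_that("MGF files round-trip spectra", {
  study <- default_study()
  path <- tempfile(fileext = ".mgf")
  write_mgf(study$spectra, path)
  back <- read_mgf(path)
  expect_equal(length(back), length(study$spectra))
  orig_keys <- vapply(study$spectra, function(s) s$key, character(1))
  back_keys <- vapply(back, function(s) s$key, character(1))
  expect_setequal(back_keys, orig_keys)
  for (s in back) {
    o <- study$spectra[[s$key]]
    expect_equal(s$mz, o$mz, tolerance = 1e-4)
    expect_equal(classify_spectrum(s), classify_spectrum(o))
  }
})
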