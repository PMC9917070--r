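# Tiered feature annotation against the library target list.

feat <- function(mz, rt, sample = "S1", area = 1e5, id = NULL) {
  data.frame(sample_id = sample, mz = mz, rt_min = rt, area = area,
             feature_id = if (is.null(id)) sprintf("f%04.0f", mz) else id,
             stringsAsFactors = FALSE)
}

test_that("the target list covers analytes plus collapsed conjugates", {
  lib <- ba_library()
  t_full <- build_target_list(lib)
  expect_equal(sum(t_full$kind == "analyte"), 46)
  expect_lte(nrow(t_full), 46 + 92)             # before-collapse upper bound
  # conjugates of isomeric analytes collapse to one target per formula
  expect_false(anyDuplicated(t_full$formula[t_full$kind == "conjugate"]) > 0)
  cdca_so3 <- t_full[t_full$target_name == "CDCA+SO3", ]
  expect_equal(nrow(cdca_so3), 1)
  expect_equal(cdca_so3$mz, 471.2422, tolerance = 1e-4)
  expect_equal(nrow(build_target_list(lib, character(0))), 46)
})

test_that("features fall into the correct tier", {
  lib <- ba_library()
  targets <- build_target_list(lib)
  gca_mz <- lib$mz[lib$name == "GCA"]
  gca_rt <- lib$reference_rt_min[lib$name == "GCA"]
  features <- rbind(
    feat(391.2850, 25.3, id = "cdca_iso"),       # CDCA-type formula, off-RT
    feat(471.2412, 25.3, id = "cdca_sulf"),      # CDCA+SO3 by exact mass
    feat(gca_mz * (1 + 3e-6), gca_rt + 0.02, id = "gca_id"),
    feat(gca_mz * (1 + 11e-6), gca_rt, id = "too_far")   # 11 ppm out
  )
  ann <- annotate_features(features, targets)
  ann <- ann[match(features$feature_id, ann$feature_id), ]
  expect_equal(ann$tier, c("isomer", "conjugate_tentative", "identified",
                           "unassigned"))
  expect_equal(ann$target_name[1], "CDCA isomer")
  expect_equal(ann$target_name[2], "CDCA+SO3")
  expect_equal(ann$ppm[2], -2.1, tolerance = 0.1)
  expect_equal(ann$target_name[3], "GCA")
  expect_equal(ann$delta_rt[3], 0.02, tolerance = 1e-9)
  expect_true(is.na(ann$delta_rt[1]))            # no delta RT outside identified
})

test_that("annotation is a function of the inputs and unique per feature", {
  study <- default_study()
  targets <- build_target_list(ba_library())
  f <- study$features
  a1 <- annotate_features(f, targets)
  a2 <- annotate_features(f[sample(nrow(f)), ], targets)
  expect_equal(nrow(a1), nrow(f))
  expect_false(anyDuplicated(a1$feature_id) > 0)
  expect_identical(a1, a2)                       # input order is irrelevant
})

test_that("shrinking the ppm tolerance never adds annotations", {
  study <- default_study()
  targets <- build_target_list(ba_library())
  n_assigned <- vapply(c(10, 5, 2, 1, 0.5), function(tol) {
    a <- annotate_features(study$features, targets, ppm_tol = tol)
    sum(a$tier != "unassigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("planted truth is recovered tier-exactly with zero decoy hits", {
  study <- default_study()
  ann <- annotate_features(study$features, build_target_list(ba_library()))
  truth <- study$truth[match(ann$feature_id, study$truth$feature_id), ]
  expect_true(all(ann$tier[truth$kind == "standard"] == "identified"))
  # identified features carry their own planted name
  std <- truth$kind == "standard"
  expect_identical(ann$target_name[std], truth$label[std])
  expect_true(all(ann$tier[truth$kind == "isomer"] == "isomer"))
  expect_true(all(ann$tier[truth$kind == "conjugate"] == "conjugate_tentative"))
  expect_true(all(ann$tier[truth$kind == "decoy"] == "unassigned"))
})

test_that("isomer groups are formula-keyed and RT-ordered", {
  iso <- isomer_reference()
  features <- do.call(rbind, lapply(seq_len(nrow(iso)), function(i) {
    feat(mz_mh_minus(iso$formula[i]), iso$rt_min[i],
         id = sprintf("iso_%02d", i))
  }))
  ann <- annotate_features(features, build_target_list(ba_library()))
  groups <- group_isomers(ann)
  expect_setequal(names(groups), unique(iso$formula))
  keto_dca <- groups[["C24H38O5"]]
  expect_equal(nrow(keto_dca), 7)
  expect_false(is.unsorted(keto_dca$rt_min))
  expect_true(all(keto_dca$target_name == "keto-DCA isomer"))
  # equal-RT members keep a stable order by feature id
  tie <- rbind(feat(mz_mh_minus("C24H40O4"), 25.3, id = "b_feat"),
               feat(mz_mh_minus("C24H40O4"), 25.3, id = "a_feat"))
  gt <- group_isomers(annotate_features(tie, build_target_list(ba_library())))
  expect_equal(gt[["C24H40O4"]]$feature_id, c("a_feat", "b_feat"))
})
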