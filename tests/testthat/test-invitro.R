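# Metabolite calling against no-cofactor controls and plasma cross-matching.

test_that("planted incubation metabolites are called with correct deltas", {
  iv <- default_invitro()
  lib <- ba_library()
  gcdca <- iv$runs[["GCDCA"]]
  calls <- call_metabolites(gcdca$full, gcdca$controls, gcdca$parent)
  expect_equal(nrow(calls), 12)
  expect_equal(sum(calls$delta_name == "hydroxylation"), 7)
  expect_equal(sum(calls$delta_name == "oxidation_to_keto"), 4)
  expect_equal(sum(calls$delta_name == "dihydroxylation"), 1)
  expect_true(all(calls$cofactor_dependence == "NADPH"))

  lca <- iv$runs[["LCA"]]
  calls <- call_metabolites(lca$full, lca$controls, lca$parent)
  expect_equal(nrow(calls), 12)
  expect_equal(sum(calls$delta_name == "dihydroxylation"), 6)
  expect_equal(sum(calls$delta_name == "hydroxylation"), 4)
  expect_equal(sum(calls$delta_name == "oxidation_to_keto"), 1)
  sulf <- calls[calls$delta_name == "sulfation", ]
  expect_equal(nrow(sulf), 1)
  expect_equal(sulf$cofactor_dependence, "PAPS")

  cdca <- iv$runs[["CDCA"]]
  calls <- call_metabolites(cdca$full, cdca$controls, cdca$parent)
  expect_setequal(calls$delta_name, c("hydroxylation", "sulfation"))
})

test_that("background features and the parent itself are never called", {
  lib <- analyte_library(ba_library())
  parent <- lib[lib$name == "CDCA", ]
  met_mz <- mz_mh_minus(apply_delta(parent$formula, "hydroxylation"))
  base <- data.frame(sample_id = "inc", mz = c(parent$mz, met_mz),
                     rt_min = c(28.7, 14.3), area = c(1e6, 2e5))
  # metabolite present equally in full and both controls: background
  same <- call_metabolites(base, list(no_NADP = base, no_PAPS = base), parent)
  expect_equal(nrow(same), 0)
  expect_error(call_metabolites(base, list(), parent), "control")
  # with proper controls, calls exist, none at the parent formula
  ctrl <- base[1, , drop = FALSE]
  calls <- call_metabolites(base, list(no_NADP = ctrl, no_PAPS = base), parent)
  expect_gt(nrow(calls), 0)
  expect_false(parent$formula %in% calls$formula)
  delta_space <- vapply(invitro_deltas(), function(d) {
    format_formula(apply_delta(parent$formula, d))
  }, character(1))
  expect_true(all(calls$formula %in% delta_space))
  expect_true(all(calls$cofactor_dependence == "NADPH"))
})

test_that("raising the fold threshold never adds calls", {
  iv <- default_invitro()
  dca <- iv$runs[["DCA"]]
  n_calls <- vapply(c(2, 5, 20, 1e6), function(thr) {
    nrow(call_metabolites(dca$full, dca$controls, dca$parent,
                          fold_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("cross-matching pairs identical formulas within the RT window", {
  plasma <- data.frame(feature_id = c("p1", "p2"),
                       target_formula = c("C24H40O5", "C24H40O5"),
                       rt_min = c(14.3, 18.9))
  calls <- data.frame(parent = c("CDCA", "UDCA"),
                      delta_name = "hydroxylation",
                      formula = c("C24H40O5", "C24H40O5"),
                      rt = c(14.4, 16.9))
  m <- cross_match(plasma, calls, rt_tol = 0.3)
  expect_equal(nrow(m), 1)
  expect_equal(m$plasma_id, "p1")
  expect_equal(m$parent, "CDCA")
  # identical formula 2 min apart stays unmatched
  far <- cross_match(plasma[2, ], calls[2, ], rt_tol = 0.3)
  expect_equal(nrow(far), 0)
  # one-to-one: two plasma peaks cannot claim the same call
  both <- data.frame(feature_id = c("a", "b"),
                     target_formula = "C24H40O5", rt_min = c(14.2, 14.4))
  m2 <- cross_match(both, calls[1, ], rt_tol = 0.3)
  expect_equal(nrow(m2), 1)
})

test_that("the default scenario yields exactly four plasma coincidences", {
  res <- default_pipeline()
  expect_equal(nrow(res$invitro_matches), 4)
  expect_setequal(
    paste(res$invitro_matches$parent, res$invitro_matches$delta_name),
    c("GCDCA hydroxylation", "CDCA hydroxylation",
      "UDCA hydroxylation", "DCA oxidation_to_keto")
  )
  # mirrors the study design: no sulfate call ever matches plasma
  expect_false(any(res$invitro_matches$delta_name == "sulfation"))
})
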