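# End-to-end orchestration: library annotation, MS/MS reconciliation,
# internal-standard normalization, differential screening, and (optionally)
# in-vitro metabolite calling with plasma cross-matching. All thresholds live
# in one parameter list so every stage sees the same tolerances.

#' Pipeline parameter set
#'
#' One source of truth for the workflow thresholds: 10 ppm mass tolerance,
#' 0.30 min identified-tier RT tolerance, p < 0.05 with fold change > 2 for
#' significance, sulfation + glucuronidation as the conjugate search space,
#' and the 75 vs 600 mg/kg contrast.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  params <- list(
    ppm_tol = 10,
    rt_tol = 0.3,
    rt_cluster_gap = 0.25,
    p_threshold = 0.05,
    fc_threshold = 2,
    two_sided_fc = FALSE,
    var_equal = TRUE,
    deltas = c("sulfation", "glucuronidation"),
    lo = "75",
    hi = "600",
    fragment_tol = 0.01,
    min_rel_intensity = 1.0,
    invitro_fold_threshold = 5,
    invitro_rt_window = 0.2,
    cross_match_rt_tol = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  params[names(dots)] <- dots
  params
}

#' Run the semi-targeted profiling pipeline
#'
#' @param features Feature data.frame over all samples (see
#'   [read_features()]); an empty table yields empty outputs and a zero-count
#'   summary.
#' @param design data.frame `sample_id`, `group`.
#' @param spectra Optional named list of `ba_spectrum` objects; features point
#'   into it via their `msms_key` column.
#' @param invitro Optional in-vitro suite as returned by
#'   [make_invitro_suite()] (fields `runs`, each with `parent`, `full`,
#'   `controls`).
#' @param library Library data.frame.
#' @param params Parameter list from [pipeline_params()].
#' @param out_dir Optional directory; when set, the annotation, differential,
#'   MS/MS reconciliation, in-vitro match and summary tables are written as
#'   CSVs there.
#' @return List: `annotations`, `is_areas`, `collated`, `results`,
#'   `msms_report`, `invitro_calls`, `invitro_matches`, `summary` (named
#'   counts of significant targets per tier), `manifest`.
#' @export
run_pipeline <- function(features, design, spectra = NULL, invitro = NULL,
                         library = ba_library(), params = pipeline_params(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  features <- validate_features(features)
  targets <- build_target_list(library, params$deltas)
  ann <- annotate_features(features, targets,
                           ppm_tol = params$ppm_tol, rt_tol = params$rt_tol)

  msms_report <- data.frame()
  if (!is.null(spectra) && length(spectra) > 0) {
    cls_table <- classify_spectra(spectra, tol = params$fragment_tol,
                                  min_rel_intensity = params$min_rel_intensity)
    idx <- which(!is.na(ann$msms_key) &
                   ann$tier %in% c("isomer", "conjugate_tentative") &
                   ann$msms_key %in% cls_table$key)
    if (length(idx) > 0) {
      first <- idx[!duplicated(ann[idx, c("msms_key", "target_name")])]
      msms_report <- do.call(rbind, lapply(first, function(i) {
        cls <- cls_table$msms_class[cls_table$key == ann$msms_key[i]]
        rec <- reconcile_annotation(ann[i, , drop = FALSE], cls, library)
        data.frame(
          msms_key = ann$msms_key[i],
          mass_assignment = ann$target_name[i],
          target_formula = ann$target_formula[i],
          msms_class = cls,
          flag = rec$msms_flag,
          reconciled_name = rec$target_name,
          stringsAsFactors = FALSE
        )
      }))
      rownames(msms_report) <- NULL
    }
  }

  is_areas <- match_internal_standards(features, is_library(library),
                                       ppm_tol = params$ppm_tol,
                                       rt_tol = params$rt_tol)
  collated <- collate_targets(ann, rt_cluster_gap = params$rt_cluster_gap)
  results <- differential_screen(
    collated, design, is_areas, library = library,
    lo = params$lo, hi = params$hi,
    p_threshold = params$p_threshold, fc_threshold = params$fc_threshold,
    two_sided_fc = params$two_sided_fc, var_equal = params$var_equal
  )
  summary <- summarize_profile(results, p_threshold = params$p_threshold,
                               fc_threshold = params$fc_threshold,
                               two_sided_fc = params$two_sided_fc)

  invitro_calls <- data.frame()
  invitro_matches <- data.frame()
  if (!is.null(invitro)) {
    invitro_calls <- do.call(rbind, lapply(invitro$runs, function(r) {
      call_metabolites(r$full, r$controls, r$parent,
                       ppm_tol = params$ppm_tol,
                       fold_threshold = params$invitro_fold_threshold,
                       rt_window = params$invitro_rt_window)
    }))
    rownames(invitro_calls) <- NULL
    if (nrow(results) > 0) {
      plasma_sig <- results[results$significant &
                              results$tier %in%
                                c("isomer", "conjugate_tentative"), ,
                            drop = FALSE]
      invitro_matches <- cross_match(plasma_sig, invitro_calls,
                                     rt_tol = params$cross_match_rt_tol)
    }
  }

  manifest <- list(
    params = params,
    n_features = nrow(features),
    n_samples = length(unique(features$sample_id)),
    n_spectra = length(spectra),
    started = t0,
    finished = Sys.time()
  )
  out <- list(annotations = ann, is_areas = is_areas, collated = collated,
              results = results, msms_report = msms_report,
              invitro_calls = invitro_calls,
              invitro_matches = invitro_matches,
              summary = summary, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ann, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "differential.csv"),
                     row.names = FALSE)
    utils::write.csv(msms_report, file.path(out_dir, "msms_reconciliation.csv"),
                     row.names = FALSE)
    utils::write.csv(invitro_matches, file.path(out_dir, "invitro_matches.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(tier = names(summary),
                                n_significant = as.integer(summary)),
                     file.path(out_dir, "summary_counts.csv"),
                     row.names = FALSE)
  }
  out
}
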