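# Metabolite calling from S9/microsome incubations and cross-matching of the
# called metabolites to plasma features. A full incubation (all cofactors) is
# compared against no-NADP+ and no-PAPS controls: a feature at a parent+delta
# exact mass is a metabolite when its area exceeds fold_threshold times the
# best explanation available from the controls, and the cofactor dependence
# follows from which single control lacks it (oxidative chemistry needs the
# NADPH-regenerating system, sulfation needs PAPS).

#' Default biotransformation vocabularies for incubation screening
#'
#' Oxidative conditions: +O, +2O, +O-2H, -2H, -O; sulfation: +SO3.
#'
#' @return Character vector of delta names understood by
#'   [biotransform_delta()].
#' @export
invitro_deltas <- function() {
  c("hydroxylation", "dihydroxylation", "oxidation_to_keto",
    "dehydrogenation", "dehydroxylation", "sulfation")
}

#' Call metabolites of one parent from an incubation run set
#'
#' @param full Feature data.frame of the full (all cofactors) incubation run.
#' @param controls Named list of control feature data.frames; names must be
#'   among `"no_NADP"`, `"no_PAPS"`. At least one control is required.
#' @param parent One analyte row of the library (or a list with `name` and
#'   `formula`).
#' @param deltas Delta names to search (default [invitro_deltas()]). Deltas
#'   that cannot apply to the parent formula (negative counts) are skipped.
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @param fold_threshold Minimum area ratio of the full run over the
#'   control floor for a call (default 5).
#' @param rt_window RT co-window in minutes used when looking the candidate up
#'   in the controls (default 0.2).
#' @return data.frame of calls: `parent`, `delta_name`, `formula`, `mz`,
#'   `rt`, `area`, `ppm`, `fold_over_control` (`Inf` when absent from every
#'   control), `cofactor_dependence` (`"NADPH"`, `"PAPS"`, or `NA` when the
#'   controls do not separate it).
#' @export
call_metabolites <- function(full, controls, parent,
                             deltas = invitro_deltas(), ppm_tol = 10,
                             fold_threshold = 5, rt_window = 0.2) {
  if (length(controls) == 0) {
    stop("at least one control run (no_NADP / no_PAPS) is required")
  }
  stopifnot(all(names(controls) %in% c("no_NADP", "no_PAPS")))
  full <- validate_features(full)
  controls <- lapply(controls, validate_features)
  parent_formula <- format_formula(as_formula(parent$formula))

  calls <- list()
  for (d in deltas) {
    met_formula <- tryCatch(apply_delta(parent$formula, d),
                            error = function(e) NULL)
    if (is.null(met_formula)) next
    if (format_formula(met_formula) == parent_formula) next
    mz_t <- mz_mh_minus(met_formula)
    hits <- which(abs(ppm_error(full$mz, mz_t)) <= ppm_tol)
    for (i in hits) {
      ctrl_area <- vapply(controls, function(ctl) {
        sel <- abs(ppm_error(ctl$mz, mz_t)) <= ppm_tol &
          abs(ctl$rt_min - full$rt_min[i]) <= rt_window
        if (any(sel)) max(ctl$area[sel]) else 0
      }, numeric(1))
      floor_area <- min(ctrl_area)
      if (full$area[i] < fold_threshold * floor_area) next
      depleted <- ctrl_area < full$area[i] / fold_threshold
      dep <- NA_character_
      if (all(c("no_NADP", "no_PAPS") %in% names(controls))) {
        if (depleted[["no_NADP"]] && !depleted[["no_PAPS"]]) dep <- "NADPH"
        if (depleted[["no_PAPS"]] && !depleted[["no_NADP"]]) dep <- "PAPS"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        parent = parent$name,
        delta_name = d,
        formula = format_formula(met_formula),
        mz = full$mz[i],
        rt = full$rt_min[i],
        area = full$area[i],
        ppm = ppm_error(full$mz[i], mz_t),
        fold_over_control = if (floor_area > 0) full$area[i] / floor_area
                            else Inf,
        cofactor_dependence = dep,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(calls) == 0) {
    return(data.frame(parent = character(0), delta_name = character(0),
                      formula = character(0), mz = numeric(0), rt = numeric(0),
                      area = numeric(0), ppm = numeric(0),
                      fold_over_control = numeric(0),
                      cofactor_dependence = character(0)))
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-match plasma annotations with in-vitro metabolite calls
#'
#' Candidate pairs share an identical elemental formula and lie within
#' `rt_tol` minutes of each other; pairs are then made one-to-one greedily by
#' smallest RT difference.
#'
#' @param plasma data.frame of plasma annotations of interest (typically the
#'   significant isomer/conjugate tiers) with columns `target_formula` (or
#'   `formula`), `rt_min` (or `rt`) and an identifier column.
#' @param calls Output of [call_metabolites()] (rows from several parents may
#'   be concatenated).
#' @param rt_tol Maximum RT difference in minutes (default 0.3).
#' @return data.frame of matched pairs: plasma identifier/formula/RT, call
#'   parent/delta/RT, and `delta_rt`. Zero rows when nothing matches.
#' @export
cross_match <- function(plasma, calls, rt_tol = 0.3) {
  empty <- data.frame(plasma_id = character(0), formula = character(0),
                      plasma_rt = numeric(0), parent = character(0),
                      delta_name = character(0), invitro_rt = numeric(0),
                      delta_rt = numeric(0))
  if (nrow(plasma) == 0 || nrow(calls) == 0) {
    return(empty)
  }
  p_formula <- if ("target_formula" %in% names(plasma)) plasma$target_formula
               else plasma$formula
  p_rt <- if ("rt_min" %in% names(plasma)) plasma$rt_min else plasma$rt
  p_id <- if ("feature_id" %in% names(plasma)) plasma$feature_id
          else if ("target_key" %in% names(plasma)) plasma$target_key
          else as.character(seq_len(nrow(plasma)))

  pairs <- expand.grid(p = seq_len(nrow(plasma)), c = seq_len(nrow(calls)))
  pairs <- pairs[p_formula[pairs$p] == calls$formula[pairs$c], , drop = FALSE]
  pairs$drt <- abs(p_rt[pairs$p] - calls$rt[pairs$c])
  pairs <- pairs[pairs$drt <= rt_tol, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(empty)
  }
  pairs <- pairs[order(pairs$drt), , drop = FALSE]
  used_p <- logical(nrow(plasma))
  used_c <- logical(nrow(calls))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!used_p[pairs$p[k]] && !used_c[pairs$c[k]]) {
      keep[k] <- TRUE
      used_p[pairs$p[k]] <- TRUE
      used_c[pairs$c[k]] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    plasma_id = p_id[pairs$p],
    formula = p_formula[pairs$p],
    plasma_rt = p_rt[pairs$p],
    parent = calls$parent[pairs$c],
    delta_name = calls$delta_name[pairs$c],
    invitro_rt = calls$rt[pairs$c],
    delta_rt = p_rt[pairs$p] - calls$rt[pairs$c],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plasma_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
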