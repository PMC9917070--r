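# Tiered library annotation. A feature is
#   identified            -- matches a standard's exact mass AND retention time,
#   isomer                -- matches a library formula's exact mass but elutes
#                            elsewhere (|delta RT| > rt_tol),
#   conjugate_tentative   -- matches a library formula plus a phase-II mass
#                            shift (sulfation/glucuronidation by default),
#   unassigned            -- matches nothing within the ppm tolerance.
# The default tolerances are 10 ppm for mass and 0.30 min for retention time.

#' Build the annotation target list
#'
#' One target per analyte (distinct reference RTs are kept so isomeric
#' standards such as CA / ACA / muricholic acids remain distinguishable), plus
#' one target per distinct (analyte formula, conjugation delta) pair --
#' conjugates of isomeric analytes share a formula and are collapsed into a
#' single target named after the formula's `isomer_group` exemplar (e.g.
#' `"CDCA+SO3"` covers the sulfates of all six di-OH standards).
#'
#' @param library Library data.frame from [ba_library()] (analyte rows are
#'   selected internally).
#' @param deltas Character vector of biotransformation names used for
#'   conjugate discovery; default sulfation and glucuronidation. Empty vector
#'   gives the analyte targets only.
#' @return data.frame with columns `target_name`, `formula`, `mz`
#'   (theoretical \[M-H\]-), `kind` (`"analyte"`/`"conjugate"`), `delta_name`,
#'   `ref_rt`, `conjugation_class`, `group_label`.
#' @export
build_target_list <- function(library,
                              deltas = c("sulfation", "glucuronidation")) {
  ana <- analyte_library(library)
  targets <- data.frame(
    target_name = ana$name,
    formula = ana$formula,
    mz = ana$mz,
    kind = "analyte",
    delta_name = NA_character_,
    ref_rt = ana$reference_rt_min,
    conjugation_class = ana$conjugation_class,
    group_label = ana$isomer_group,
    stringsAsFactors = FALSE
  )
  suffix <- c(sulfation = "+SO3", glucuronidation = "+Gluc")
  for (d in deltas) {
    conj_formula <- vapply(ana$formula, function(f) {
      format_formula(apply_delta(f, d))
    }, character(1))
    keep <- !duplicated(conj_formula)
    sfx <- if (d %in% names(suffix)) suffix[[d]] else paste0("+", d)
    targets <- rbind(targets, data.frame(
      target_name = paste0(ana$isomer_group[keep], sfx),
      formula = unname(conj_formula[keep]),
      mz = vapply(conj_formula[keep], mz_mh_minus, numeric(1), USE.NAMES = FALSE),
      kind = "conjugate",
      delta_name = d,
      ref_rt = NA_real_,
      conjugation_class = ana$conjugation_class[keep],
      group_label = ana$isomer_group[keep],
      stringsAsFactors = FALSE
    ))
  }
  rownames(targets) <- NULL
  targets
}

#' Annotate LC-MS features against the target list
#'
#' Each feature receives its best target by smallest |ppm error|, ties broken
#' by smallest |RT - reference RT| (conjugate targets, which have no reference
#' RT, sort last), then lexicographic target name. The tier follows from the
#' winning target: an analyte target within `rt_tol` is `identified`; an
#' analyte formula matched outside `rt_tol` is an `isomer` and is renamed to
#' the formula group's exemplar plus `" isomer"`; a conjugate target gives
#' `conjugate_tentative`. Features matching nothing are `unassigned`. Output
#' order is deterministic: features are sorted internally by (mz, rt).
#'
#' @param features data.frame with columns `sample_id`, `mz`, `rt_min`,
#'   `area`, optional `msms_key` and `feature_id` (generated when absent).
#' @param targets Target list from [build_target_list()].
#' @param ppm_tol Mass tolerance in ppm (default 10, > 0).
#' @param rt_tol Retention-time tolerance in minutes for the identified tier
#'   (default 0.3, > 0).
#' @return The feature columns plus `tier`, `target_name`, `matched_name`
#'   (the specific library entry that won the tie-break), `target_formula`,
#'   `delta_name`, `ppm`, `delta_rt` (NA except for the identified tier) and
#'   `group_label`.
#' @export
annotate_features <- function(features, targets, ppm_tol = 10, rt_tol = 0.3) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  features <- validate_features(features)
  n <- nrow(features)
  ann <- data.frame(
    features,
    tier = rep("unassigned", n),
    target_name = rep(NA_character_, n),
    matched_name = rep(NA_character_, n),
    target_formula = rep(NA_character_, n),
    delta_name = rep(NA_character_, n),
    ppm = rep(NA_real_, n),
    delta_rt = rep(NA_real_, n),
    group_label = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0 || nrow(targets) == 0) {
    return(ann)
  }
  ord <- order(features$mz, features$rt_min)
  ann <- ann[ord, , drop = FALSE]

  ppm_mat <- outer(ann$mz, targets$mz, function(o, t) (o - t) / t * 1e6)
  for (i in seq_len(nrow(ann))) {
    cand <- which(abs(ppm_mat[i, ]) <= ppm_tol)
    if (length(cand) == 0) next
    drt <- abs(ann$rt_min[i] - targets$ref_rt[cand])
    drt[is.na(drt)] <- Inf
    pick <- cand[order(abs(ppm_mat[i, cand]), drt, targets$target_name[cand])][1]
    dr <- abs(ann$rt_min[i] - targets$ref_rt[pick])
    ann$matched_name[i] <- targets$target_name[pick]
    ann$target_formula[i] <- targets$formula[pick]
    ann$delta_name[i] <- targets$delta_name[pick]
    ann$ppm[i] <- ppm_mat[i, pick]
    ann$group_label[i] <- targets$group_label[pick]
    if (targets$kind[pick] == "conjugate") {
      ann$tier[i] <- "conjugate_tentative"
      ann$target_name[i] <- targets$target_name[pick]
    } else if (!is.na(dr) && dr <= rt_tol) {
      ann$tier[i] <- "identified"
      ann$target_name[i] <- targets$target_name[pick]
      ann$delta_rt[i] <- ann$rt_min[i] - targets$ref_rt[pick]
    } else {
      ann$tier[i] <- "isomer"
      ann$target_name[i] <- paste(targets$group_label[pick], "isomer")
    }
  }
  rownames(ann) <- NULL
  ann
}

#' Group isomer-tier annotations by elemental formula
#'
#' @param annotations Output of [annotate_features()].
#' @return Named list (one element per formula with at least one isomer-tier
#'   annotation) of annotation data.frames ordered by RT ascending, ties kept
#'   stable by `feature_id`.
#' @export
group_isomers <- function(annotations) {
  iso <- annotations[annotations$tier == "isomer", , drop = FALSE]
  if (nrow(iso) == 0) {
    return(stats::setNames(list(), character(0)))
  }
  out <- split(iso, iso$target_formula)
  lapply(out, function(g) {
    g <- g[order(g$rt_min, g$feature_id), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

# Schema validation for feature tables; reports the offending row/field so a
# malformed CSV aborts with a usable diagnostic.
validate_features <- function(features) {
  required <- c("sample_id", "mz", "rt_min", "area")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table misses column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("mz", "rt_min", "area")) {
    v <- features[[col]]
    if (!is.numeric(v)) {
      stop("feature column '", col, "' is not numeric")
    }
    bad <- which(is.na(v) | (col == "mz" & v <= 0) |
                   (col != "mz" & v < 0))
    if (length(bad) > 0) {
      stop("invalid value in feature column '", col, "' at row ", bad[1],
           " (", v[bad[1]], ")")
    }
  }
  if (is.null(features$msms_key)) {
    features$msms_key <- rep(NA_character_, nrow(features))
  }
  if (is.null(features$feature_id)) {
    features$feature_id <- sprintf("F%05d", seq_len(nrow(features)))
  }
  features
}

#' Read a feature table CSV
#'
#' Columns `sample_id`, `mz`, `rt_min`, `area`, optional `msms_key`; the
#' schema is validated and the first offending row is reported on failure.
#'
#' @param path CSV path.
#' @return Validated feature data.frame.
#' @export
read_features <- function(path) {
  validate_features(utils::read.csv(path, stringsAsFactors = FALSE))
}
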