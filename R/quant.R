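# Internal-standard normalization and dose-group differential screening.
# Peak areas are normalized to a deuterated internal standard (area ratio
# analyte/IS), the 75 vs 600 mg/kg contrast is tested with a two-sample
# Student t-test on the ratios, and a target is called significant when
# p < 0.05 and the fold change of group-mean ratios exceeds 2.

#' Assign a deuterated internal standard to an analyte
#'
#' Deterministic rule mirroring how an analyst pairs standards: an internal
#' standard whose name is `d<n>-<analyte>` wins outright; otherwise the
#' internal standard of the same conjugation class with the nearest reference
#' RT; if the class has no internal standard, the globally nearest-RT one.
#'
#' @param name Analyte or target name (used for the exact-name preference).
#' @param conjugation_class `"unconjugated"`, `"glycine"`, `"taurine"`, or
#'   `NA` to skip the class preference.
#' @param rt Retention time (minutes) of the analyte peak.
#' @param is_lib Internal-standard rows, e.g. `is_library(ba_library())`.
#' @return The chosen internal-standard name.
#' @export
assign_internal_standard <- function(name, conjugation_class, rt, is_lib) {
  if (nrow(is_lib) == 0) {
    stop("internal-standard library is empty")
  }
  exact <- is_lib$name[sub("^d[0-9]+-", "", is_lib$name) == name]
  if (length(exact) > 0) {
    return(exact[1])
  }
  pool <- is_lib
  if (!is.na(conjugation_class) &&
      any(is_lib$conjugation_class == conjugation_class)) {
    pool <- is_lib[is_lib$conjugation_class == conjugation_class, , drop = FALSE]
  }
  pool$name[order(abs(pool$reference_rt_min - rt), pool$name)][1]
}

#' Locate internal-standard peaks in a feature table
#'
#' Matches features to the deuterium-shifted theoretical m/z and reference RT
#' of each internal standard; when several features of a sample fall in the
#' window the largest area is taken.
#'
#' @param features Feature data.frame (see [read_features()]).
#' @param is_lib Internal-standard library rows.
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @param rt_tol RT tolerance in minutes (default 0.3).
#' @return data.frame `sample_id`, `is_name`, `area` (absent combinations mean
#'   the IS peak was not found in that sample).
#' @export
match_internal_standards <- function(features, is_lib, ppm_tol = 10,
                                     rt_tol = 0.3) {
  out <- list()
  for (i in seq_len(nrow(is_lib))) {
    sel <- abs(ppm_error(features$mz, is_lib$mz[i])) <= ppm_tol &
      abs(features$rt_min - is_lib$reference_rt_min[i]) <= rt_tol
    if (!any(sel)) next
    hit <- features[sel, , drop = FALSE]
    best <- do.call(rbind, lapply(split(hit, hit$sample_id), function(h) {
      h[which.max(h$area), c("sample_id", "area"), drop = FALSE]
    }))
    best$is_name <- is_lib$name[i]
    out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(0), area = numeric(0),
                      is_name = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample_id", "is_name", "area")]
}

#' Normalize analyte areas to internal-standard areas
#'
#' @param areas data.frame `sample_id`, `area` for one target (one row per
#'   sample).
#' @param is_areas data.frame `sample_id`, `area` for the assigned internal
#'   standard.
#' @return data.frame `sample_id`, `ratio`, `flag` -- ratio is `NA` and the
#'   flag `"is_missing"` for samples without an IS peak (or with IS area 0).
#' @export
normalize_areas <- function(areas, is_areas) {
  m <- match(areas$sample_id, is_areas$sample_id)
  is_area <- is_areas$area[m]
  ok <- !is.na(is_area) & is_area > 0
  data.frame(
    sample_id = areas$sample_id,
    ratio = ifelse(ok, areas$area / is_area, NA_real_),
    flag = ifelse(ok, NA_character_, "is_missing"),
    stringsAsFactors = FALSE
  )
}

#' Two-group differential test on area ratios
#'
#' Student's two-sample equal-variance t-test (the behaviour of the vendor
#' statistics tools this workflow mirrors; Welch available via `var_equal =
#' FALSE`) on untransformed area ratios. Fold change is the ratio of group
#' means, high over low. Significance: p < `p_threshold` and fold change >
#' `fc_threshold` (or < 1/`fc_threshold` when `two_sided_fc` is on).
#'
#' @param ratios_lo,ratios_hi Numeric vectors of per-sample area ratios for
#'   the low- and high-dose groups; at least 2 finite values per side.
#' @param p_threshold,fc_threshold Significance thresholds (defaults 0.05, 2).
#' @param two_sided_fc Also call decreases (fold change < 1/`fc_threshold`)
#'   significant (default `FALSE`).
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return One-row data.frame: `p_value`, `fold_change`, `mean_lo`, `mean_hi`,
#'   `significant`, `flag`. Degenerate inputs: two identical constant groups
#'   give p = 1; a zero low-group mean gives an undefined fold change,
#'   flagged `"fc_undefined"`.
#' @export
differential_test <- function(ratios_lo, ratios_hi, p_threshold = 0.05,
                              fc_threshold = 2, two_sided_fc = FALSE,
                              var_equal = TRUE) {
  ratios_lo <- ratios_lo[is.finite(ratios_lo)]
  ratios_hi <- ratios_hi[is.finite(ratios_hi)]
  if (length(ratios_lo) < 2 || length(ratios_hi) < 2) {
    stop("need at least 2 finite ratios per group")
  }
  m_lo <- mean(ratios_lo)
  m_hi <- mean(ratios_hi)
  if (stats::sd(ratios_lo) == 0 && stats::sd(ratios_hi) == 0) {
    p <- if (m_lo == m_hi) 1 else 0
  } else {
    p <- stats::t.test(ratios_hi, ratios_lo, var.equal = var_equal)$p.value
  }
  flag <- NA_character_
  if (m_lo == 0) {
    fc <- NA_real_
    flag <- "fc_undefined"
  } else {
    fc <- m_hi / m_lo
  }
  sig <- !is.na(fc) & p < p_threshold &
    (fc > fc_threshold | (two_sided_fc & fc < 1 / fc_threshold))
  data.frame(p_value = p, fold_change = fc, mean_lo = m_lo, mean_hi = m_hi,
             significant = sig, flag = flag, stringsAsFactors = FALSE)
}

#' Collate annotated features into per-target area series
#'
#' Identified-tier annotations collate by compound name. Isomer- and
#' conjugate-tier annotations of the same label are split into RT clusters
#' (single linkage: a gap larger than `rt_cluster_gap` between consecutive
#' sorted RTs starts a new cluster), since the same formula can elute as
#' several distinct chromatographic species. `rt_cluster_gap` must exceed
#' twice the within-study RT scatter and stay below the smallest real isomer
#' separation; 0.25 min suits the synthetic scenarios.
#'
#' @param annotations Output of [annotate_features()] over all samples.
#' @param rt_cluster_gap Cluster-breaking RT gap in minutes (default 0.25).
#' @return data.frame with one row per (target, RT cluster, sample):
#'   `target_key`, `target_name`, `tier`, `target_formula`, `delta_name`,
#'   `group_label`, `rt` (cluster median), `sample_id`, `area`.
#' @export
collate_targets <- function(annotations, rt_cluster_gap = 0.25) {
  ann <- annotations[annotations$tier != "unassigned", , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(target_key = character(0), target_name = character(0),
                      tier = character(0), target_formula = character(0),
                      delta_name = character(0), group_label = character(0),
                      rt = numeric(0), sample_id = character(0),
                      area = numeric(0)))
  }
  pieces <- lapply(split(ann, paste(ann$target_name, ann$tier)), function(g) {
    g <- g[order(g$rt_min, g$feature_id), , drop = FALSE]
    if (g$tier[1] == "identified") {
      g$cluster <- 1L
    } else {
      g$cluster <- cumsum(c(1L, diff(g$rt_min) > rt_cluster_gap))
    }
    do.call(rbind, lapply(split(g, g$cluster), function(cl) {
      data.frame(
        target_key = sprintf("%s @%.2f", cl$target_name[1],
                             stats::median(cl$rt_min)),
        target_name = cl$target_name[1],
        tier = cl$tier[1],
        target_formula = cl$target_formula[1],
        delta_name = cl$delta_name[1],
        group_label = cl$group_label[1],
        rt = stats::median(cl$rt_min),
        sample_id = cl$sample_id,
        area = cl$area,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Differential screen across all collated targets
#'
#' For every target the internal standard is assigned (exact name, then
#' conjugation class + nearest RT), areas are normalized to IS area ratios
#' per sample, and the low/high dose groups are compared with
#' [differential_test()].
#'
#' @param collated Output of [collate_targets()].
#' @param design data.frame `sample_id`, `group` (labels such as `"75"`,
#'   `"600"`).
#' @param is_areas Output of [match_internal_standards()].
#' @param library Library data.frame (for IS assignment metadata).
#' @param lo,hi Group labels contrasted (defaults `"75"` and `"600"`,
#'   the lowest and highest doses).
#' @inheritParams differential_test
#' @return data.frame with one row per target: identification columns, the
#'   assigned `is_name`, `n_lo`/`n_hi` finite ratios, and the
#'   [differential_test()] columns.
#' @export
differential_screen <- function(collated, design, is_areas,
                                library = ba_library(), lo = "75", hi = "600",
                                p_threshold = 0.05, fc_threshold = 2,
                                two_sided_fc = FALSE, var_equal = TRUE) {
  if (nrow(collated) == 0) {
    return(data.frame())
  }
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  is_lib <- is_library(library)
  ana <- analyte_library(library)
  res <- lapply(split(collated, collated$target_key), function(g) {
    # class preference from the matched formula group's parent chemistry
    # (conjugate-tier targets inherit the class of the analyte group)
    cls <- unique(ana$conjugation_class[ana$isomer_group == g$group_label[1]])[1]
    is_name <- assign_internal_standard(g$target_name[1], cls,
                                        g$rt[1], is_lib)
    is_a <- is_areas[is_areas$is_name == is_name, , drop = FALSE]
    ratios <- normalize_areas(g[, c("sample_id", "area")], is_a)
    grp <- design$group[match(ratios$sample_id, design$sample_id)]
    r_lo <- ratios$ratio[grp == lo]
    r_hi <- ratios$ratio[grp == hi]
    if (sum(is.finite(r_lo)) < 2 || sum(is.finite(r_hi)) < 2) {
      return(NULL)
    }
    cbind(
      g[1, c("target_key", "target_name", "tier", "target_formula",
             "delta_name", "group_label", "rt")],
      data.frame(is_name = is_name,
                 n_lo = sum(is.finite(r_lo)), n_hi = sum(is.finite(r_hi))),
      differential_test(r_lo, r_hi, p_threshold = p_threshold,
                        fc_threshold = fc_threshold,
                        two_sided_fc = two_sided_fc, var_equal = var_equal)
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame())
  }
  out <- out[order(out$tier, out$target_name, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize significant targets per annotation tier
#'
#' @param results Output of [differential_screen()] (or any data.frame with
#'   `tier`, `delta_name`, `p_value`, `fold_change`).
#' @param p_threshold,fc_threshold Thresholds re-applied here so printed
#'   tables can be re-screened at other cutoffs (defaults 0.05 and 2).
#' @param two_sided_fc Count decreases as well (default `FALSE`).
#' @return Named integer vector: `identified`, `isomer`, `sulfate`,
#'   `glucuronide` counts of significant targets (all zero for empty input).
#' @export
summarize_profile <- function(results, p_threshold = 0.05, fc_threshold = 2,
                              two_sided_fc = FALSE) {
  counts <- c(identified = 0L, isomer = 0L, sulfate = 0L, glucuronide = 0L)
  if (is.null(results) || nrow(results) == 0) {
    return(counts)
  }
  sig <- !is.na(results$fold_change) & results$p_value < p_threshold &
    (results$fold_change > fc_threshold |
       (two_sided_fc & results$fold_change < 1 / fc_threshold))
  r <- results[sig, , drop = FALSE]
  counts["identified"] <- sum(r$tier == "identified")
  counts["isomer"] <- sum(r$tier == "isomer")
  counts["sulfate"] <- sum(r$tier == "conjugate_tentative" &
                             r$delta_name == "sulfation", na.rm = TRUE)
  counts["glucuronide"] <- sum(r$tier == "conjugate_tentative" &
                                 r$delta_name == "glucuronidation", na.rm = TRUE)
  counts
}
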