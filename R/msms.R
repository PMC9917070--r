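# Conjugate-class assignment from MS/MS spectra. Glycine, taurine and sulfate
# conjugates of bile acids each leave characteristic low-mass product ions in
# negative mode; the steroid backbone itself fragments poorly, so these
# diagnostic ions carry essentially all of the class information. All
# diagnostic masses are computed from elemental formulas -- never typed in as
# literals -- so they stay consistent with the mass engine.

#' Diagnostic product-ion table
#'
#' Theoretical m/z of the class-diagnostic fragments, computed from formulas:
#' deprotonated glycine C2H4NO2- (74.0248), deprotonated taurine C2H6NO3S-
#' (124.0074) with its companions C2H3SO3- (106.9808), HSO3- (80.9652) and the
#' SO3 radical anion (79.9574), and HSO4- (96.9601) for sulfate esters. Note
#' HSO3- computes to 80.9652, which displays as 80.97 at two decimals; the
#' table keeps the computed value.
#'
#' @return data.frame with columns `class`, `ion`, `mz`, `primary` (`TRUE`
#'   for the ion sufficient on its own to call the class).
#' @export
diagnostic_ions <- function() {
  rbind(
    data.frame(class = "glycine", ion = "glycine [M-H]-",
               mz = mz_mh_minus("C2H5NO2"), primary = TRUE),
    data.frame(class = "taurine", ion = "taurine [M-H]-",
               mz = mz_mh_minus("C2H7NO3S"), primary = TRUE),
    data.frame(class = "taurine", ion = "C2H3SO3-",
               mz = mz_mh_minus("C2H4O3S"), primary = FALSE),
    data.frame(class = "taurine", ion = "HSO3-",
               mz = mz_mh_minus("H2SO3"), primary = FALSE),
    data.frame(class = "taurine", ion = "SO3-.",
               mz = monoisotopic_mass("SO3") + ELECTRON_MASS, primary = FALSE),
    data.frame(class = "sulfate", ion = "HSO4-",
               mz = mz_mh_minus("H2SO4"), primary = TRUE)
  )
}

#' Construct an MS/MS spectrum object
#'
#' @param key Spectrum identifier (links feature tables to spectra).
#' @param precursor_mz Precursor m/z.
#' @param mz,intensity Fragment m/z values and relative intensities (0-100);
#'   stored sorted by m/z.
#' @return List of class `ba_spectrum`.
#' @export
ba_spectrum <- function(key, precursor_mz, mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            all(intensity <= 100))
  ord <- order(mz)
  structure(list(key = key, precursor_mz = precursor_mz,
                 mz = mz[ord], intensity = intensity[ord]),
            class = "ba_spectrum")
}

#' Classify a spectrum into a conjugate class
#'
#' Decision rule (precedence taurine > sulfate > glycine):
#' * `taurine` if deprotonated taurine (124.0074) is present, or at least two
#'   ions of the taurine set (124.0074 / 106.9808 / 80.9652 / 79.9574) are;
#'   single low-mass sulfur ions are ambiguous with sulfate chemistry, hence
#'   the two-ion requirement for the companions;
#' * else `sulfate` if HSO4- (96.9601) is present;
#' * else `glycine` if deprotonated glycine (74.0248) is present;
#' * else `none`.
#'
#' A fragment "is present" when a peak lies within `tol` of its theoretical
#' m/z with relative intensity at or above `min_rel_intensity`. The result is
#' invariant to peak order and to peaks below the intensity threshold.
#'
#' @param s A `ba_spectrum` (or list with `mz` and `intensity`).
#' @param tol Fragment mass tolerance in Da (default 0.01, suited to TOF
#'   MS/MS accuracy at low m/z).
#' @param min_rel_intensity Minimum relative intensity (percent of base peak)
#'   for a diagnostic ion to count (default 1).
#' @return One of `"glycine"`, `"taurine"`, `"sulfate"`, `"none"`.
#' @export
classify_spectrum <- function(s, tol = 0.01, min_rel_intensity = 1.0) {
  ions <- diagnostic_ions()
  mz <- s$mz[s$intensity >= min_rel_intensity]
  present <- vapply(ions$mz, function(m) any(abs(mz - m) <= tol), logical(1))
  tau <- ions$class == "taurine"
  if (any(present & tau & ions$primary) || sum(present & tau) >= 2) {
    return("taurine")
  }
  if (any(present & ions$class == "sulfate")) {
    return("sulfate")
  }
  if (any(present & ions$class == "glycine")) {
    return("glycine")
  }
  "none"
}

#' Classify a set of spectra
#'
#' @param spectra List of `ba_spectrum` objects.
#' @inheritParams classify_spectrum
#' @return data.frame with `key`, `precursor_mz`, `msms_class`.
#' @export
classify_spectra <- function(spectra, tol = 0.01, min_rel_intensity = 1.0) {
  data.frame(
    key = vapply(spectra, function(s) s$key, character(1)),
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    msms_class = vapply(spectra, classify_spectrum, character(1),
                        tol = tol, min_rel_intensity = min_rel_intensity),
    stringsAsFactors = FALSE
  )
}

# Conjugation class implied by a mass-based annotation: sulfate for a
# sulfation delta, otherwise the amino-acid class of the matched library
# group (glucuronide-tentative rows imply no diagnostic class).
implied_msms_class <- function(delta_name, conjugation_class) {
  if (!is.na(delta_name) && delta_name == "sulfation") {
    return("sulfate")
  }
  if (!is.na(conjugation_class) && conjugation_class %in% c("glycine", "taurine")) {
    return(conjugation_class)
  }
  "none"
}

#' Reconcile a mass-based annotation with its MS/MS classification
#'
#' When the spectrum class contradicts the exact-mass assignment, the formula
#' is reinterpreted isomerically: the conjugate delta of the observed class is
#' subtracted from the assigned formula, and if a valid (non-negative) parent
#' formula remains, the annotation is re-labelled as that class's conjugate of
#' the corresponding formula group -- flagged `msms_reassigned`. The classic
#' case is a putative GLCA+SO3 (C26H43NO7S) whose spectrum shows the taurine
#' ion at 124.01: the same elemental formula is a taurine conjugate of a
#' keto-DCA-type C24H38O5 skeleton. If no isomeric reinterpretation exists the
#' annotation is kept and flagged `msms_conflict`. Agreeing or uninformative
#' (`"none"`) classifications leave the annotation unchanged.
#'
#' @param a One annotation row (data.frame) from [annotate_features()], tier
#'   `conjugate_tentative` or `isomer`.
#' @param cls Classification from [classify_spectrum()].
#' @param library Library data.frame, used to name the reinterpreted formula
#'   group.
#' @return The annotation row with `msms_class` and `msms_flag` columns added
#'   (flag one of `NA`, `"msms_reassigned"`, `"msms_conflict"`), and
#'   `target_name`/`target_formula` rewritten on reassignment.
#' @export
reconcile_annotation <- function(a, cls, library = ba_library()) {
  stopifnot(nrow(a) == 1)
  a$msms_class <- cls
  a$msms_flag <- NA_character_
  if (!a$tier %in% c("conjugate_tentative", "isomer")) {
    return(a)
  }
  ana <- analyte_library(library)
  group_class <- unique(ana$conjugation_class[ana$isomer_group == a$group_label])
  if (length(group_class) != 1) group_class <- NA_character_
  implied <- implied_msms_class(a$delta_name, group_class)
  if (cls == "none" || cls == implied) {
    return(a)
  }
  delta <- switch(cls,
    sulfate = "sulfation",
    glycine = "glycine_amidation",
    taurine = "taurine_amidation"
  )
  parent <- tryCatch(
    apply_delta(a$target_formula, -biotransform_delta(delta)),
    error = function(e) NULL
  )
  if (is.null(parent) || (!is.na(parent["H"]) && parent["H"] < 1) ||
      is.na(parent["C"]) || parent["C"] < 1) {
    a$msms_flag <- "msms_conflict"
    return(a)
  }
  parent_formula <- format_formula(parent)
  ana <- analyte_library(library)
  grp <- unique(ana$isomer_group[ana$formula == parent_formula])
  parent_label <- if (length(grp) == 1) paste(grp, "isomer") else parent_formula
  a$target_name <- paste0(cls, " conjugate of ", parent_label)
  a$msms_flag <- "msms_reassigned"
  a
}
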