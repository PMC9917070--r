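# The packaged bile-acid standards library: the 46 analytes of the commercial
# standard mix plus the 14 deuterated internal standards. The compound names
# and conjugation chemistry are field-standard; elemental formulas were
# compiled from standard references and are cross-validated at load time by
# the amidation and hydroxyl-class arithmetic below. The reference retention
# times are synthetic scenario data (the gradient the library mimics elutes
# taurine conjugates first, then glycine conjugates, then unconjugated
# species, with tri-OH < di-OH < mono-OH within each class on C18); they are
# not measured values.

#' Load the packaged bile-acid / internal-standard library
#'
#' Reads a library CSV (by default the one shipped with the package), parses
#' every formula, computes theoretical \[M-H\]- m/z (shifted by
#' n x 1.00627675 Da for deuterated internal standards), and runs structural
#' self-consistency checks. Load aborts if any check fails.
#'
#' Checks performed:
#' * exactly 46 analyte entries and 14 internal-standard entries for the
#'   packaged file (skipped for user files);
#' * every glycine conjugate's formula equals its parent formula plus
#'   C2H3NO, and every taurine conjugate's equals parent plus C2H5NO2S;
#' * unconjugated, non-keto, non-nor species carry the canonical backbone:
#'   mono-OH C24H40O3, di-OH C24H40O4, tri-OH C24H40O5;
#' * `isomer_group` is a function of the formula among analytes.
#'
#' @param path CSV path; defaults to the packaged library. Columns: `name`,
#'   `formula`, `conjugation_class` (unconjugated/glycine/taurine),
#'   `hydroxyl_class` (mono/di/tri/other), `parent_name`, `parent_formula`,
#'   `isomer_group`, `reference_rt_min`, `is_internal_standard`,
#'   `deuterium_count`.
#' @param expect_counts Check the 46 + 14 entry counts (default `TRUE` for the
#'   packaged file).
#' @return A data.frame with the file columns plus `neutral_mass` and `mz`
#'   (theoretical \[M-H\]-, deuterium-shifted for internal standards).
#' @export
ba_library <- function(path = NULL, expect_counts = is.null(path)) {
  if (is.null(path)) {
    path <- system.file("extdata", "ba_library.csv", package = "baprofiler")
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("name", "formula", "conjugation_class", "hydroxyl_class",
                "parent_name", "parent_formula", "isomer_group",
                "reference_rt_min", "is_internal_standard", "deuterium_count")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols) > 0) {
    stop("library file misses column(s): ", paste(missing_cols, collapse = ", "))
  }
  lib$is_internal_standard <- as.logical(lib$is_internal_standard)

  if (expect_counts) {
    n_analyte <- sum(!lib$is_internal_standard)
    n_is <- sum(lib$is_internal_standard)
    if (n_analyte != 46L || n_is != 14L) {
      stop("expected 46 analytes + 14 internal standards, got ",
           n_analyte, " + ", n_is)
    }
  }
  if (anyDuplicated(lib$name)) {
    stop("duplicate library names: ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "))
  }

  parsed <- lapply(lib$formula, parse_formula)
  lib$neutral_mass <- vapply(parsed, monoisotopic_mass, numeric(1))
  lib$mz <- vapply(lib$formula, mz_mh_minus, numeric(1)) +
    lib$deuterium_count * DEUTERIUM_SHIFT

  # amidation consistency: conjugate formula = parent formula + amino-acid delta
  for (i in seq_len(nrow(lib))) {
    cls <- lib$conjugation_class[i]
    if (cls %in% c("glycine", "taurine") && nzchar(lib$parent_formula[i])) {
      delta <- if (cls == "glycine") "glycine_amidation" else "taurine_amidation"
      expect <- apply_delta(lib$parent_formula[i], delta)
      if (format_formula(expect) != format_formula(parsed[[i]])) {
        stop("amidation inconsistency for ", lib$name[i], ": ",
             lib$parent_formula[i], " + ", cls, " gives ",
             format_formula(expect), ", file says ", lib$formula[i])
      }
    }
  }

  # hydroxyl-class arithmetic for unconjugated canonical backbones
  backbone <- c(mono = "C24H40O3", di = "C24H40O4", tri = "C24H40O5")
  chk <- !lib$is_internal_standard &
    lib$conjugation_class == "unconjugated" &
    lib$hydroxyl_class %in% names(backbone)
  bad <- chk & lib$formula != backbone[lib$hydroxyl_class]
  if (any(bad)) {
    stop("hydroxyl-class arithmetic fails for: ",
         paste(lib$name[bad], collapse = ", "))
  }

  # isomer_group must be consistent within a formula (analytes only)
  ana <- lib[!lib$is_internal_standard, ]
  grp_per_formula <- tapply(ana$isomer_group, ana$formula,
                            function(g) length(unique(g)))
  if (any(grp_per_formula > 1)) {
    stop("isomer_group is not unique per formula: ",
         paste(names(grp_per_formula)[grp_per_formula > 1], collapse = ", "))
  }

  lib
}

#' Internal-standard entries of a library
#' @param lib Library data.frame from [ba_library()].
#' @return The internal-standard rows.
#' @export
is_library <- function(lib) lib[lib$is_internal_standard, , drop = FALSE]

#' Analyte entries of a library
#' @param lib Library data.frame from [ba_library()].
#' @return The analyte (non-internal-standard) rows.
#' @export
analyte_library <- function(lib) lib[!lib$is_internal_standard, , drop = FALSE]
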