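# Truth-annotated synthetic studies. The generator emulates the statistical
# structure the analysis assumes: a 4-dose x 3-replicate plasma study over the
# 46-standard library with 14 deuterated internal standards, isomeric and
# phase-II conjugate features planted at reference-table retention times and
# fold changes, multiplicative (lognormal) abundance noise, ppm-scale mass
# error, retention-time jitter, decoy features, diagnostic MS/MS spectra, and
# a suite of S9 incubation runs with no-cofactor controls.

# truncated normal by rejection; vectorised, deterministic under set.seed
rtruncnorm <- function(n, sd, max_abs) {
  if (sd <= 0) {
    return(numeric(n))
  }
  out <- stats::rnorm(n, 0, sd)
  bad <- which(abs(out) > max_abs)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- which(abs(out) > max_abs)
  }
  out
}

# lognormal multiplicative noise parameterised by the coefficient of
# variation; the *median* is 1, so planted medians are hit exactly
ln_noise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Default synthetic-study configuration
#'
#' Encodes the study conditions the workflow targets: 4 dose groups (75, 150,
#' 300, 600 mg/kg) in triplicate; all 46 standards and 14 internal standards
#' planted per sample; 13 standards with dose effects ([effect_reference()]);
#' the 22 isomer placements of [isomer_reference()]; the 9 significant
#' sulfates of [sulfate_reference()] plus 4 non-changing sulfates and 6
#' non-changing glucuronides; one sulfate-by-mass feature at RT 10.9 whose
#' MS/MS is that of a taurine conjugate (the class-reassignment case); 15
#' decoy features at non-library masses; 10% analytical CV; mass error
#' N(0, 3 ppm) truncated at +/-5 ppm; RT jitter N(0, 0.05 min) truncated at
#' +/-0.10 min. Dose response is a geometric ramp reaching the planted fold
#' change at 600 vs 75 mg/kg.
#'
#' @param seed Integer seed stored in the config; every generator call is
#'   fully reproducible from it.
#' @return Named list of scenario parameters.
#' @export
default_scenario <- function(seed = 17L) {
  list(
    seed = as.integer(seed),
    groups = c("75", "150", "300", "600"),
    replicates = 3L,
    baseline_area = 1e5,
    isomer_baseline = 5e4,
    conjugate_baseline = 4e4,
    decoy_baseline = 3e4,
    is_area = 5e4,
    analytical_cv = 0.10,
    mass_error_ppm_sd = 3,
    mass_error_ppm_max = 5,
    rt_jitter_sd = 0.05,
    rt_jitter_max = 0.10,
    lod = 500,
    n_decoys = 15L,
    decoy_mz_range = c(350, 550),
    decoy_exclusion_ppm = 25,
    sample_scale = NULL,          # optional per-sample injection drift
    absent_analytes = character(0),
    effects = effect_reference(),
    isomers = isomer_reference(),
    sulfates = sulfate_reference(),
    extra_sulfates = data.frame(
      label = c("keto-DCA+SO3", "CA+SO3", "CDCA+SO3", "LCA+SO3"),
      formula = c("C24H38O8S", "C24H40O8S", "C24H40O7S", "C24H40O6S"),
      rt_min = c(13.5, 15.0, 19.0, 43.5),
      fold_change = c(1, 1, 1, 1),
      stringsAsFactors = FALSE
    ),
    glucuronides = data.frame(
      label = c("CA+Gluc", "CDCA+Gluc", "CDCA+Gluc", "GCA+Gluc",
                "LCA+Gluc", "keto-DCA+Gluc"),
      formula = c("C30H48O11", "C30H48O10", "C30H48O10", "C32H51NO12",
                  "C30H48O9", "C30H46O11"),
      rt_min = c(5.6, 8.2, 9.4, 6.2, 12.9, 7.0),
      fold_change = c(1, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    ),
    misassigned = data.frame(
      label = "GLCA+SO3", formula = "C26H43NO7S", rt_min = 10.9,
      fold_change = 1.5, true_class = "taurine",
      stringsAsFactors = FALSE
    ),
    invitro = list(
      parent_area = 1e6,
      metabolite_area = 2e5,
      leakage = 0.02,
      rt_jitter_sd = 0.02,
      rt_jitter_max = 0.05,
      plan = invitro_plan()
    )
  )
}

#' Read a scenario configuration from YAML
#'
#' Fields present in the file override the defaults of [default_scenario()];
#' table-valued fields (effects, isomers, ...) are converted from YAML lists
#' of columns to data.frames.
#'
#' @param path YAML file path.
#' @param seed Seed when the file does not set one.
#' @return Scenario list.
#' @export
read_scenario <- function(path, seed = 17L) {
  cfg <- default_scenario(seed)
  user <- yaml::read_yaml(path)
  for (k in names(user)) {
    cfg[[k]] <- if (is.data.frame(cfg[[k]])) {
      as.data.frame(user[[k]], stringsAsFactors = FALSE)
    } else {
      user[[k]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' In-vitro incubation plan of the default scenario
#'
#' Metabolite placements for the nine incubated standards, following the
#' reported metabolite inventory per parent (e.g. GCDCA: seven +O, four
#' +O-2H, one +2O). Four oxidative metabolites are planted at retention times
#' coinciding with plasma isomer placements (DCA+O-2H at 15.8, CDCA+O at
#' 14.3, UDCA+O at 18.9, GCDCA+O at 9.5); every other metabolite, including
#' all sulfates, elutes at least 0.5 min from any same-formula plasma
#' feature.
#'
#' @return data.frame: `parent`, `delta_name`, `rt_min`.
#' @export
invitro_plan <- function() {
  p <- function(parent, delta, rts) {
    data.frame(parent = parent, delta_name = delta, rt_min = rts,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("CA", "hydroxylation", c(9.7, 10.6)),
    p("CA", "oxidation_to_keto", 15.3),
    p("alpha-MCA", "hydroxylation", c(7.9, 8.6, 9.2, 11.0)),
    p("alpha-MCA", "oxidation_to_keto", 12.0),
    p("beta-MCA", "hydroxylation", c(8.3, 10.0)),
    p("beta-MCA", "oxidation_to_keto", 13.0),
    p("CDCA", "hydroxylation", 14.3),
    p("CDCA", "sulfation", 20.0),
    p("DCA", "hydroxylation", c(7.4, 8.0, 9.0, 10.4, 11.3, 12.2, 13.1)),
    p("DCA", "dehydroxylation", 44.0),
    p("DCA", "oxidation_to_keto", 15.8),
    p("DCA", "sulfation", 27.8),
    p("UDCA", "hydroxylation", c(6.3, 7.0, 8.5, 9.8, 18.9)),
    p("UDCA", "sulfation", 18.3),
    p("LCA", "dihydroxylation", c(16.9, 20.8, 22.2, 24.5, 26.0, 27.2)),
    p("LCA", "hydroxylation", c(30.5, 32.0, 33.5, 36.0)),
    p("LCA", "oxidation_to_keto", 28.5),
    p("LCA", "sulfation", 39.8),
    p("GCA", "oxidation_to_keto", 10.5),
    p("GCDCA", "hydroxylation", c(5.2, 7.5, 9.5, 13.2, 14.6, 15.5, 16.4)),
    p("GCDCA", "oxidation_to_keto", c(17.9, 19.1, 20.3, 21.5)),
    p("GCDCA", "dihydroxylation", 4.6)
  )
}

# diagnostic MS/MS peak lists per conjugate class (relative intensities);
# masses come from diagnostic_ions(), never typed as literals
class_spectrum_peaks <- function(class) {
  ions <- diagnostic_ions()
  ion_mz <- function(ion) ions$mz[ions$ion == ion]
  switch(class,
    glycine = data.frame(mz = ion_mz("glycine [M-H]-"), intensity = 60),
    taurine = data.frame(
      mz = c(ion_mz("taurine [M-H]-"), ion_mz("C2H3SO3-"),
             ion_mz("HSO3-"), ion_mz("SO3-.")),
      intensity = c(55, 8, 12, 6)),
    sulfate = data.frame(
      mz = c(ion_mz("HSO4-"), ion_mz("SO3-.")),
      intensity = c(50, 4)),
    stop("no diagnostic spectrum for class '", class, "'")
  )
}

# one synthetic MS/MS spectrum: class-diagnostic ions plus weak nonspecific
# steroid-backbone peaks (below the 1% calling threshold)
make_class_spectrum <- function(key, precursor_mz, class) {
  pk <- class_spectrum_peaks(class)
  backbone <- data.frame(
    mz = precursor_mz - c(18.0106, 46.0055, 62.0004),
    intensity = c(0.8, 0.5, 0.3)
  )
  all <- rbind(pk, backbone, data.frame(mz = precursor_mz, intensity = 100))
  ba_spectrum(key, precursor_mz, all$mz, all$intensity)
}

# group multiplier: geometric ramp from 1 at the lowest dose to the planted
# fold change at the highest
dose_multiplier <- function(fc, group, groups) {
  idx <- match(group, groups) - 1L
  fc^(idx / (length(groups) - 1L))
}

# species table: one row per planted chromatographic species
scenario_species <- function(cfg, lib) {
  ana <- analyte_library(lib)
  ana <- ana[!ana$name %in% cfg$absent_analytes, , drop = FALSE]
  isl <- is_library(lib)
  fc <- cfg$effects$fold_change[match(ana$name, cfg$effects$name)]
  fc[is.na(fc)] <- 1
  msms_class <- ifelse(ana$conjugation_class %in% c("glycine", "taurine"),
                       ana$conjugation_class, NA_character_)
  species <- data.frame(
    label = ana$name,
    kind = "standard",
    formula = ana$formula,
    mz_theo = ana$mz,
    rt_ref = ana$reference_rt_min,
    baseline = cfg$baseline_area,
    fc = fc,
    true_class = msms_class,
    stringsAsFactors = FALSE
  )
  species <- rbind(species, data.frame(
    label = isl$name, kind = "internal_standard", formula = isl$formula,
    mz_theo = isl$mz, rt_ref = isl$reference_rt_min,
    baseline = cfg$is_area, fc = 1, true_class = NA_character_
  ))
  iso <- cfg$isomers
  species <- rbind(species, data.frame(
    label = sprintf("%s isomer @%.1f", iso$group_label, iso$rt_min),
    kind = "isomer", formula = iso$formula,
    mz_theo = vapply(iso$formula, mz_mh_minus, numeric(1), USE.NAMES = FALSE),
    rt_ref = iso$rt_min, baseline = cfg$isomer_baseline,
    fc = iso$fold_change, true_class = NA_character_
  ))
  conj <- rbind(
    data.frame(label = sprintf("%s @%.1f", cfg$sulfates$label,
                               cfg$sulfates$rt_min),
               formula = cfg$sulfates$formula, rt = cfg$sulfates$rt_min,
               fc = cfg$sulfates$fold_change, true_class = "sulfate"),
    data.frame(label = sprintf("%s @%.1f", cfg$extra_sulfates$label,
                               cfg$extra_sulfates$rt_min),
               formula = cfg$extra_sulfates$formula,
               rt = cfg$extra_sulfates$rt_min,
               fc = cfg$extra_sulfates$fold_change, true_class = "sulfate"),
    data.frame(label = sprintf("%s @%.1f", cfg$glucuronides$label,
                               cfg$glucuronides$rt_min),
               formula = cfg$glucuronides$formula,
               rt = cfg$glucuronides$rt_min,
               fc = cfg$glucuronides$fold_change,
               true_class = NA_character_),
    data.frame(label = sprintf("%s @%.1f", cfg$misassigned$label,
                               cfg$misassigned$rt_min),
               formula = cfg$misassigned$formula,
               rt = cfg$misassigned$rt_min,
               fc = cfg$misassigned$fold_change,
               true_class = cfg$misassigned$true_class)
  )
  species <- rbind(species, data.frame(
    label = conj$label, kind = "conjugate", formula = conj$formula,
    mz_theo = vapply(conj$formula, mz_mh_minus, numeric(1), USE.NAMES = FALSE),
    rt_ref = conj$rt, baseline = cfg$conjugate_baseline,
    fc = conj$fc, true_class = conj$true_class
  ))
  species
}

# decoy m/z: uniform in range, rejected within the exclusion window of any
# annotatable mass (library, conjugate target space, internal standards)
draw_decoy_mz <- function(n, cfg, lib) {
  targets <- build_target_list(lib)
  protected <- c(targets$mz, is_library(lib)$mz)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n - length(out), cfg$decoy_mz_range[1],
                         cfg$decoy_mz_range[2])
    ok <- vapply(cand, function(m) {
      all(abs((m - protected) / protected * 1e6) > cfg$decoy_exclusion_ppm)
    }, logical(1))
    out <- c(out, cand[ok])
  }
  out
}

#' Generate a synthetic plasma dose-response study
#'
#' Areas are drawn lognormally around `baseline x dose multiplier` (the
#' multiplier ramps geometrically to the planted fold change at the highest
#' dose); m/z values are the theoretical \[M-H\]- masses perturbed by
#' truncated-normal ppm error; retention times are the references plus
#' truncated-normal jitter. Internal standards are planted per sample at
#' their deuterium-shifted masses, conjugate and isomer species at their
#' configured retention times, and decoys at non-annotatable masses. MS/MS
#' spectra with the correct diagnostic ions are attached (via `msms_key`) to
#' every glycine/taurine standard and every sulfate-type conjugate. Features
#' below the limit of detection are dropped.
#'
#' @param cfg Scenario list from [default_scenario()].
#' @param library Library data.frame (defaults to the packaged one).
#' @return List: `features` (one data.frame over all samples), `design`
#'   (`sample_id`, `group`), `spectra` (list of `ba_spectrum`), `truth`
#'   (one row per feature: planted identity, tier, formula, fold change,
#'   expected significance, true ppm/RT errors), `config`.
#' @export
make_plasma_study <- function(cfg = default_scenario(), library = ba_library()) {
  set.seed(cfg$seed)
  species <- scenario_species(cfg, library)
  decoy_mz <- draw_decoy_mz(cfg$n_decoys, cfg, library)
  if (cfg$n_decoys > 0) {
    species <- rbind(species, data.frame(
      label = sprintf("decoy-%02d", seq_len(cfg$n_decoys)),
      kind = "decoy", formula = NA_character_, mz_theo = decoy_mz,
      rt_ref = stats::runif(cfg$n_decoys, 3, 45),
      baseline = cfg$decoy_baseline, fc = 1, true_class = NA_character_
    ))
  }
  design <- data.frame(
    sample_id = paste0("S", rep(cfg$groups, each = cfg$replicates), "_r",
                       rep(seq_len(cfg$replicates), length(cfg$groups))),
    group = rep(cfg$groups, each = cfg$replicates),
    stringsAsFactors = FALSE
  )
  scale <- cfg$sample_scale
  if (is.null(scale)) scale <- rep(1, nrow(design))
  stopifnot(length(scale) == nrow(design))

  ns <- nrow(species)
  rows <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    mult <- dose_multiplier(species$fc, design$group[s], cfg$groups)
    area <- species$baseline * mult * scale[s] * ln_noise(ns, cfg$analytical_cv)
    eps <- rtruncnorm(ns, cfg$mass_error_ppm_sd, cfg$mass_error_ppm_max)
    jit <- rtruncnorm(ns, cfg$rt_jitter_sd, cfg$rt_jitter_max)
    rows[[s]] <- data.frame(
      sample_id = design$sample_id[s],
      feature_id = sprintf("%s_%03d", design$sample_id[s], seq_len(ns)),
      mz = species$mz_theo * (1 + eps * 1e-6),
      rt_min = species$rt_ref + jit,
      area = area,
      msms_key = ifelse(is.na(species$true_class), NA_character_,
                        species$label),
      label = species$label,
      kind = species$kind,
      formula = species$formula,
      fc = species$fc,
      true_class = species$true_class,
      ppm_true = eps,
      rt_jitter = jit,
      stringsAsFactors = FALSE
    )
  }
  all_rows <- do.call(rbind, rows)
  keep <- all_rows$area >= cfg$lod
  all_rows <- all_rows[keep, , drop = FALSE]

  features <- all_rows[, c("sample_id", "feature_id", "mz", "rt_min",
                           "area", "msms_key")]
  rownames(features) <- NULL
  truth <- data.frame(
    feature_id = all_rows$feature_id,
    sample_id = all_rows$sample_id,
    label = all_rows$label,
    kind = all_rows$kind,
    formula = all_rows$formula,
    planted_fc = all_rows$fc,
    expect_significant = all_rows$kind %in%
      c("standard", "isomer", "conjugate") & all_rows$fc > 2,
    true_class = all_rows$true_class,
    ppm_error_true = all_rows$ppm_true,
    rt_jitter_true = all_rows$rt_jitter,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL

  sp_keys <- unique(species[!is.na(species$true_class),
                            c("label", "mz_theo", "true_class")])
  spectra <- lapply(seq_len(nrow(sp_keys)), function(i) {
    make_class_spectrum(sp_keys$label[i], sp_keys$mz_theo[i],
                        sp_keys$true_class[i])
  })
  names(spectra) <- sp_keys$label

  list(features = features, design = design, spectra = spectra,
       truth = truth, config = cfg)
}

#' Generate the in-vitro incubation suite
#'
#' For each incubated parent, three runs are produced: `full` (all cofactors;
#' parent plus every planned metabolite), `no_NADP` (sulfation metabolites
#' retained, oxidative ones at the leakage level) and `no_PAPS` (the
#' converse). Masses and retention times are perturbed like the plasma study.
#'
#' @param cfg Scenario list (uses its `invitro` block and noise settings).
#' @param library Library data.frame.
#' @return List: `runs` -- named list (per parent) of
#'   `list(parent, full, controls = list(no_NADP, no_PAPS))` feature tables --
#'   and `truth` (the expanded plan with formulas and expected cofactor
#'   dependence).
#' @export
make_invitro_suite <- function(cfg = default_scenario(),
                               library = ba_library()) {
  set.seed(cfg$seed + 1L)
  iv <- cfg$invitro
  plan <- iv$plan
  ana <- analyte_library(library)
  unknown <- setdiff(plan$parent, ana$name)
  if (length(unknown) > 0) {
    stop("unknown incubation parent(s): ", paste(unknown, collapse = ", "))
  }
  plan$parent_formula <- ana$formula[match(plan$parent, ana$name)]
  plan$formula <- vapply(seq_len(nrow(plan)), function(i) {
    format_formula(apply_delta(plan$parent_formula[i], plan$delta_name[i]))
  }, character(1))
  plan$mz_theo <- vapply(plan$formula, mz_mh_minus, numeric(1),
                         USE.NAMES = FALSE)
  plan$dependence <- ifelse(plan$delta_name == "sulfation", "PAPS", "NADPH")

  feature_rows <- function(mz_theo, rt_ref, area) {
    n <- length(mz_theo)
    if (n == 0) {
      return(data.frame(sample_id = character(0), mz = numeric(0),
                        rt_min = numeric(0), area = numeric(0)))
    }
    eps <- rtruncnorm(n, cfg$mass_error_ppm_sd, cfg$mass_error_ppm_max)
    jit <- rtruncnorm(n, iv$rt_jitter_sd, iv$rt_jitter_max)
    data.frame(
      sample_id = "incubation",
      mz = mz_theo * (1 + eps * 1e-6),
      rt_min = rt_ref + jit,
      area = area * ln_noise(n, cfg$analytical_cv),
      stringsAsFactors = FALSE
    )
  }

  runs <- lapply(split(plan, plan$parent), function(pl) {
    parent_row <- ana[ana$name == pl$parent[1], ]
    parent_feat <- function() {
      feature_rows(parent_row$mz, parent_row$reference_rt_min, iv$parent_area)
    }
    oxidative <- pl$delta_name != "sulfation"
    mk_run <- function(level_ox, level_sulf) {
      area <- iv$metabolite_area *
        ifelse(oxidative, level_ox, level_sulf)
      present <- area > 0
      rbind(parent_feat(),
            feature_rows(pl$mz_theo[present], pl$rt_min[present],
                         area[present]))
    }
    list(
      parent = parent_row,
      full = mk_run(1, 1),
      controls = list(
        no_NADP = mk_run(iv$leakage, 1),
        no_PAPS = mk_run(1, iv$leakage)
      )
    )
  })
  list(runs = runs, truth = plan)
}

#' Simulate a Gaussian-peak extracted-ion chromatogram
#'
#' @param peaks data.frame with `rt` (apex, minutes), `height`, `sigma`
#'   (minutes).
#' @param rt_range Trace limits in minutes.
#' @param step Grid step in minutes (default 0.005).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0).
#' @param baseline Constant baseline offset added to the trace (default 0);
#'   a positive offset keeps additive noise from clipping at zero.
#' @param target_mz Recorded on the trace object (cosmetic; default `NA`).
#' @return A `ba_trace` object.
#' @export
simulate_xic <- function(peaks, rt_range = c(0, 55), step = 0.005,
                         noise_sd = 0, baseline = 0, target_mz = NA_real_) {
  rt <- seq(rt_range[1], rt_range[2], by = step)
  y <- rep(baseline, length(rt))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$height[i] *
      exp(-0.5 * ((rt - peaks$rt[i]) / peaks$sigma[i])^2)
  }
  if (noise_sd > 0) {
    y <- pmax(y + stats::rnorm(length(rt), 0, noise_sd), 0)
  }
  structure(list(rt = rt, intensity = y, target_mz = target_mz,
                 ppm_window = NA_real_), class = "ba_trace")
}

#' Simulate centroided run points for XIC extraction
#'
#' Produces a long-format point table (`rt_min`, `mz`, `intensity`) with one
#' centroid per scan per compound while its Gaussian elution profile is above
#' `cutoff`.
#'
#' @param compounds data.frame with `mz`, `rt` (apex), `height`, `sigma`.
#' @param rt_range,step Acquisition grid.
#' @param cutoff Minimum intensity emitted (default 1).
#' @return data.frame usable as the `run` argument of [extract_xic()].
#' @export
simulate_run_points <- function(compounds, rt_range = c(0, 55), step = 0.02,
                                cutoff = 1) {
  grid <- seq(rt_range[1], rt_range[2], by = step)
  out <- lapply(seq_len(nrow(compounds)), function(i) {
    y <- compounds$height[i] *
      exp(-0.5 * ((grid - compounds$rt[i]) / compounds$sigma[i])^2)
    sel <- y >= cutoff
    data.frame(rt_min = grid[sel], mz = compounds$mz[i], intensity = y[sel])
  })
  # emit every scan at least once so the acquisition grid is complete
  anchor <- data.frame(rt_min = grid, mz = 0.0, intensity = 0.0)
  res <- rbind(do.call(rbind, out), anchor)
  res[order(res$rt_min, res$mz), ]
}

#' Simulate null (no-effect) targets and return their t-test p-values
#'
#' Each target gets lognormal area ratios with median 1 in both groups; the
#' p-values come from [differential_test()], so the fraction below 0.05
#' estimates the screen's type-I error under the study's noise model.
#'
#' @param n_targets Number of null targets (default 1000).
#' @param n_per_group Replicates per group (default 3).
#' @param cv Coefficient of variation of the ratios (default 0.10).
#' @param seed RNG seed.
#' @return Numeric vector of p-values, length `n_targets`.
#' @export
simulate_null_pvalues <- function(n_targets = 1000, n_per_group = 3,
                                  cv = 0.10, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_targets), function(i) {
    differential_test(ln_noise(n_per_group, cv),
                      ln_noise(n_per_group, cv))$p_value
  }, numeric(1))
}
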