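# Elemental-formula arithmetic and monoisotopic mass computation for
# negative-mode small-molecule HRMS. Everything downstream (library targets,
# conjugate discovery, diagnostic MS/MS ions) is derived from these constants.

# Monoisotopic masses of the most abundant isotope of each element handled in
# this domain (CODATA/IUPAC 2021 atomic mass evaluation, truncated to 8
# decimals). 12C is exactly 12 by definition.
ISOTOPE_MASS <- c(
  C = 12.0,
  H = 1.00782503,
  D = 2.01410178,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200
)

# m/z bookkeeping constants. [M-H]- uses the proton mass (electron retained by
# the anion), so the deprotonation shift is -1.00727646, not -1.00782503.
PROTON_MASS <- 1.00727646
ELECTRON_MASS <- 0.00054858

# Mass gained per H -> D substitution in a deuterated internal standard.
DEUTERIUM_SHIFT <- unname(ISOTOPE_MASS["D"] - ISOTOPE_MASS["H"])

#' Parse an elemental formula string
#'
#' Parses formulas such as `"C24H40O7S"` into a named count vector. Only the
#' elements with a known monoisotopic mass (C, H, D, N, O, S, P) are accepted;
#' a count of 1 may be omitted.
#'
#' @param text A single formula string, e.g. `"C26H43NO5"`. An empty string is
#'   allowed and yields the empty formula (mass zero).
#' @return A named integer vector of element counts, ordered C, H, then the
#'   remaining elements alphabetically (Hill order).
#' @examples
#' parse_formula("H2O")
#' parse_formula("C24H40O7S")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("malformed formula string: '", text, "'")
  }
  syms <- sub("[0-9]*$", "", tokens)
  unknown <- setdiff(syms, names(ISOTOPE_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " in '", text, "'")
  }
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  counts <- tapply(cnts, syms, sum)
  normalize_formula(stats::setNames(as.integer(counts), names(counts)))
}

# Canonical ordering (C, H, then alphabetical) with zero counts dropped.
normalize_formula <- function(counts) {
  counts <- counts[counts != 0]
  elems <- names(counts)
  lead <- intersect(c("C", "H"), elems)
  rest <- sort(setdiff(elems, c("C", "H")))
  out <- counts[c(lead, rest)]
  stats::setNames(as.integer(out), names(out))
}

# Accept either a formula string or an already-parsed count vector.
as_formula <- function(f) {
  if (is.character(f)) {
    return(parse_formula(f))
  }
  if (is.null(names(f)) && length(f) > 0) {
    stop("formula count vectors must be named by element symbol")
  }
  unknown <- setdiff(names(f), names(ISOTOPE_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(f < 0)) {
    stop("negative element counts in formula")
  }
  normalize_formula(stats::setNames(as.integer(f), names(f)))
}

#' Format an element-count vector back into a formula string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A single string in Hill order; `""` for the empty formula.
#' @export
format_formula <- function(counts) {
  counts <- normalize_formula(counts)
  if (length(counts) == 0) {
    return("")
  }
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses over the element counts.
#'
#' @param f Formula string or named count vector. The empty formula has mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0105646
#' monoisotopic_mass("C24H40O7S") # 472.2494747
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) {
    return(0)
  }
  sum(ISOTOPE_MASS[names(f)] * f)
}

#' Theoretical m/z of the deprotonated molecular ion [M-H]-
#'
#' Negative electrospray convention: m/z = neutral monoisotopic mass minus the
#' proton mass 1.00727646 Da (the electron stays with the anion), charge 1.
#'
#' @param f Formula string or named count vector; must contain at least one H.
#' @return m/z of the singly deprotonated anion.
#' @examples
#' mz_mh_minus("C24H40O7S") # 471.2422 (CDCA+SO3)
#' @export
mz_mh_minus <- function(f) {
  f <- as_formula(f)
  if (is.na(f["H"]) || f["H"] < 1L) {
    stop("cannot deprotonate a formula without hydrogen: '",
         format_formula(f), "'")
  }
  monoisotopic_mass(f) - PROTON_MASS
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z (vectorised).
#' @param theoretical Theoretical m/z; must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`, signed.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive")
  }
  (observed - theoretical) / theoretical * 1e6
}

# Fixed phase-I/phase-II biotransformation deltas as signed element-count
# vectors. Sulfation transfers SO3, glucuronidation C6H8O6 (glucuronic acid
# minus water), amidation with glycine/taurine adds the amino acid minus water,
# and the oxidative vocabulary covers hydroxylation (+O), oxidation of a
# hydroxyl to a ketone (+O-2H applied relative to the reduced parent: here
# -2H+O on the parent formula), dehydrogenation (-2H) and dehydroxylation (-O).
BIOTRANSFORM_DELTAS <- list(
  sulfation          = c(S = 1L, O = 3L),
  glucuronidation    = c(C = 6L, H = 8L, O = 6L),
  hydroxylation      = c(O = 1L),
  dihydroxylation    = c(O = 2L),
  oxidation_to_keto  = c(O = 1L, H = -2L),
  dehydrogenation    = c(H = -2L),
  dehydroxylation    = c(O = -1L),
  glycine_amidation  = c(C = 2L, H = 3L, N = 1L, O = 1L),
  taurine_amidation  = c(C = 2L, H = 5L, N = 1L, O = 2L, S = 1L)
)

#' Look up a biotransformation delta by name
#'
#' @param name One of `sulfation`, `glucuronidation`, `hydroxylation`,
#'   `dihydroxylation`, `oxidation_to_keto`, `dehydrogenation`,
#'   `dehydroxylation`, `glycine_amidation`, `taurine_amidation`, or an
#'   already-built signed count vector (returned unchanged).
#' @return A signed named integer vector of element-count changes.
#' @export
biotransform_delta <- function(name) {
  if (!is.character(name)) {
    stopifnot(!is.null(names(name)))
    return(name)
  }
  d <- BIOTRANSFORM_DELTAS[[name]]
  if (is.null(d)) {
    stop("unknown biotransformation: '", name, "'")
  }
  d
}

#' Mass change of a biotransformation delta
#'
#' @param d Delta name or signed count vector.
#' @return Signed mass change in Da.
#' @export
delta_mass <- function(d) {
  d <- biotransform_delta(d)
  sum(ISOTOPE_MASS[names(d)] * d)
}

#' Apply a biotransformation delta to a formula
#'
#' Count-wise sum; mass additivity holds exactly:
#' `monoisotopic_mass(apply_delta(f, d)) == monoisotopic_mass(f) + delta_mass(d)`.
#'
#' @param f Formula string or count vector.
#' @param d Delta name (see [biotransform_delta()]) or signed count vector.
#' @return The resulting formula as a named count vector. Errors if any
#'   resulting element count would be negative (e.g. dehydroxylation of a
#'   formula with no oxygen).
#' @examples
#' format_formula(apply_delta("C24H40O4", "sulfation")) # CDCA+SO3
#' @export
apply_delta <- function(f, d) {
  f <- as_formula(f)
  d <- biotransform_delta(d)
  elems <- union(names(f), names(d))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(f)] <- out[names(f)] + f
  out[names(d)] <- out[names(d)] + d
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    stop("delta would give negative count for element(s): ",
         paste(bad, collapse = ", "), " on '", format_formula(f), "'")
  }
  normalize_formula(out)
}

#' Combine two biotransformation deltas into one signed count vector
#'
#' @param a,b Delta names or signed count vectors.
#' @return Signed count vector of the element-wise sum.
#' @export
combine_deltas <- function(a, b) {
  a <- biotransform_delta(a)
  b <- biotransform_delta(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}
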