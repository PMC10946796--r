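# Monoisotopic masses (Da). Charge-carrier deltas are stored as cation mass
# minus one electron so that theoretical m/z of +1 ions is exact.

#' Monoisotopic atomic masses
#'
#' Named vector of monoisotopic atomic masses (Da) for the elements that occur
#' in glycero- and sphingolipids, including deuterium (`D`) for isotope-labelled
#' internal standards.
#'
#' @format Named numeric vector, units Da.
#' @export
ATOMIC_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668
)

ELECTRON_MASS <- 0.000548579909
ISOTOPE_C13_DELTA <- 1.003355   # m(13C) - m(12C)
WATER_MASS <- 18.010565         # H2O monoisotopic

#' Supported adduct forms
#'
#' Table of the singly charged positive-mode adduct forms the annotation engine
#' considers: protonated, sodiated, potassiated, dehydrated-protonated, and the
#' first carbon-13 isotope peak of each. Mass deltas are cation-minus-electron
#' masses so `neutral_mass + mass_delta` is the exact theoretical m/z of a +1
#' ion.
#'
#' @return A data.frame with columns `adduct` (label), `mass_delta` (Da),
#'   `charge` and `is_isotope` (logical, carbon-13 variant).
#' @examples
#' adduct_forms()
#' @export
adduct_forms <- function() {
  # standard tabulated cation-minus-electron masses (6-decimal convention
  # used throughout adduct calculators)
  proton <- 1.007276
  sodium <- 22.989218
  potassium <- 38.963158
  base <- data.frame(
    adduct = c("M+H", "M+Na", "M+K", "M+H-H2O"),
    mass_delta = c(proton, sodium, potassium, proton - WATER_MASS),
    charge = 1L,
    is_isotope = FALSE,
    stringsAsFactors = FALSE
  )
  iso <- base
  iso$adduct <- paste0(base$adduct, "+13C")
  iso$mass_delta <- base$mass_delta + ISOTOPE_C13_DELTA
  iso$is_isotope <- TRUE
  rbind(base, iso)
}

#' Monoisotopic mass from an elemental formula
#'
#' Parses a Hill-style elemental formula (e.g. `"C41H73D7NO8P"`) and returns
#' its monoisotopic mass. Deuterium is written `D`.
#'
#' @param formula Character scalar, elemental composition.
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' formula_mass("H2O")
#' formula_mass("C41H73D7NO8P")  # deuterated PC(15:0/18:1)
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed elemental formula: ", formula)
  }
  mass <- 0
  for (tok in tokens) {
    elem <- gsub("[0-9]+", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!elem %in% names(ATOMIC_MASSES)) {
      stop("unknown element '", elem, "' in formula ", formula)
    }
    mass <- mass + n * ATOMIC_MASSES[[elem]]
  }
  mass
}

#' Theoretical m/z of a lipid under an adduct form
#'
#' @param neutral_mass Monoisotopic neutral mass (Da), or a `LipidRecord`-style
#'   list/data.frame row with a `neutral_mass` field.
#' @param adduct Adduct label, one of `adduct_forms()$adduct`.
#' @return Theoretical m/z (Da) of the singly charged ion.
#' @examples
#' theoretical_mz(formula_mass("C41H73D7NO8P"), "M+H")  # 753.6134
#' @export
theoretical_mz <- function(neutral_mass, adduct) {
  if (is.list(neutral_mass)) neutral_mass <- neutral_mass$neutral_mass
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  tab <- adduct_forms()
  idx <- match(adduct, tab$adduct)
  if (anyNA(idx)) {
    stop("unknown adduct label(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "))
  }
  neutral_mass + tab$mass_delta[idx]
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values (Da).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
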