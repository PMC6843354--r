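#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic masses (Da) used for every mass computed
#' by the package. Deuterium is listed as `D`. Platinum has a broad isotope
#' envelope, so the reference isotope must be declared explicitly: the default
#' `Pt` entry is 195Pt (the most abundant isotope, which deconvolution
#' software uses to anchor the reported monoisotopic peak); `"194Pt"` selects
#' the lighter neighbour instead.
#'
#' @param pt_isotope Reference platinum isotope, `"195Pt"` (default) or
#'   `"194Pt"`.
#' @return Named numeric vector of monoisotopic masses in Da.
#' @examples
#' element_masses()[["H"]]
#' element_masses("194Pt")[["Pt"]]
#' @export
element_masses <- function(pt_isotope = c("195Pt", "194Pt")) {
  pt_isotope <- match.arg(pt_isotope)
  m <- c(
    H  = 1.00782503,
    D  = 2.01410178,
    C  = 12.00000000,
    N  = 14.00307401,
    O  = 15.99491462,
    S  = 31.97207069,
    P  = 30.97376151,
    Cl = 34.96885271
  )
  m[["Pt"]] <- if (pt_isotope == "195Pt") 194.96479170 else 193.96268090
  m
}

# mass of a composition given as a named count vector, e.g. c(C = 5, H = 4, O = 2)
#' Mass of an elemental composition
#'
#' @param composition Named numeric vector of element counts. Element symbols
#'   must appear in [element_masses()]; `D` denotes deuterium.
#' @param pt_isotope Passed to [element_masses()].
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 10, H = 14, N = 2, O = 5)) # thymidine nucleoside
#' @export
formula_mass <- function(composition, pt_isotope = "195Pt") {
  if (length(composition) == 0) return(0)
  elems <- names(composition)
  tab <- element_masses(pt_isotope)
  unknown <- setdiff(elems, names(tab))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(tab[elems] * as.numeric(composition))
}

# add compositions (named count vectors); counts may be negative for losses
comp_add <- function(...) {
  parts <- list(...)
  out <- numeric(0)
  for (p in parts) {
    for (e in names(p)) out[e] <- (if (e %in% names(out)) out[[e]] else 0) + p[[e]]
  }
  out[out != 0]
}

.WATER <- c(H = 2, O = 1)
.HPO3  <- c(H = 1, P = 1, O = 3)

# residue (internal, dehydrated) compositions of the 20 canonical amino acids
.AA_COMP <- list(
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  V = c(C = 5,  H = 9,  N = 1, O = 1)
)

# 2'-deoxyribonucleoside compositions (free nucleoside, both OH)
.DNA_NUCLEOSIDE_COMP <- list(
  A = c(C = 10, H = 13, N = 5, O = 3),
  C = c(C = 9,  H = 13, N = 3, O = 4),
  G = c(C = 10, H = 13, N = 5, O = 4),
  T = c(C = 10, H = 14, N = 2, O = 5)
)
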