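#' Define a homobifunctional cross-linker
#'
#' Describes the chemistry of an NHS-ester style cross-linker: the elemental
#' composition added to the bridged species in its light and (optionally)
#' heavy isotope-coded form, the reactive residue classes, and the distance
#' span the linker implies between bridged residues.
#'
#' @param name Linker name (e.g. `"DSG"`).
#' @param light Named count vector: composition added by the light bridge.
#' @param heavy Composition of the heavy (deuterated) bridge, or `NULL` when
#'   no isotope-coded form exists.
#' @param reactive Character vector of reactive residue classes (one-letter
#'   codes, plus `"nterm"` for the protein N-terminal amine).
#' @param span Distance span center between bridged residues, in Angstrom.
#' @param span_tol Span tolerance in Angstrom (must be >= 0).
#' @return An object of class `crosslinker`.
#' @seealso [xl_linkers()] for the built-in DSG/DSS definitions.
#' @export
crosslinker <- function(name, light, heavy = NULL,
                        reactive = c("K", "S", "nterm"),
                        span, span_tol = 3.0) {
  stopifnot(is.character(name), length(name) == 1, span > 0, span_tol >= 0)
  structure(
    list(name = name, light = light, heavy = heavy,
         reactive = reactive, span = span, span_tol = span_tol),
    class = "crosslinker"
  )
}

#' Built-in cross-linker definitions
#'
#' DSG (di(N-succinimidyl) glutarate) and DSS (di(N-succinimidyl) suberate)
#' in their d0/d4 isotope-coded pairs. The light bridge compositions are the
#' net atoms added upon double aminolysis (C5H4O2 for DSG, C8H10O2 for DSS);
#' the d4 forms substitute four deuteriums. Spans: DSG bridges reactive
#' groups within 20.5 +/- 3.0 A, DSS within 24.2 +/- 3.0 A. Both react with
#' lysine and serine side chains and the protein N-terminal amine.
#'
#' @return Named list of [crosslinker()] objects (`DSG`, `DSS`).
#' @examples
#' doublet_delta(xl_linkers()$DSS) # 4.0251
#' @export
xl_linkers <- function() {
  list(
    DSG = crosslinker(
      "DSG",
      light = c(C = 5, H = 4, O = 2),
      heavy = c(C = 5, D = 4, O = 2),
      reactive = c("K", "S", "nterm"),
      span = 20.5, span_tol = 3.0
    ),
    DSS = crosslinker(
      "DSS",
      light = c(C = 8, H = 10, O = 2),
      heavy = c(C = 8, H = 6, D = 4, O = 2),
      reactive = c("K", "S", "nterm"),
      span = 24.2, span_tol = 3.0
    )
  )
}

#' Define a platinum adduct chemistry
#'
#' Transplatin-style Pt(II) chemistry: the bifunctional bridge (both
#' chlorides displaced, net addition Pt(NH3)2) and the monofunctional
#' "dangling" adduct (one chloride retained, Pt(NH3)2Cl). Protein targets
#' default to the electron-rich side chains Cys, Met, His, Thr; the DNA
#' target is guanine (N7 attack).
#'
#' @param name Adduct name.
#' @param protein_reactive Reactive amino-acid classes on the protein side.
#' @param include_termini Whether protein termini count as reactive sites.
#' @param dna_reactive Reactive DNA base (default `"G"`).
#' @param span Assumed bridged-heteroatom distance for restraint generation
#'   (Angstrom). The trans coordination geometry of Pt(II) places the two
#'   ligand atoms ~4 A apart; the default 5.0 +/- 2.0 A adds side-chain
#'   slack. This span is a package default, not an experimentally calibrated
#'   value.
#' @param span_tol Span tolerance in Angstrom.
#' @param pt_isotope Reference Pt isotope for mass computation.
#' @return An object of class `pt_adduct`.
#' @examples
#' ad <- pt_adduct()
#' pt_delta(ad, "bifunctional")  # 229.0179
#' pt_delta(ad, "monofunctional") # 263.9867
#' @export
pt_adduct <- function(name = "transplatin",
                      protein_reactive = c("C", "M", "H", "T"),
                      include_termini = FALSE,
                      dna_reactive = "G",
                      span = 5.0, span_tol = 2.0,
                      pt_isotope = c("195Pt", "194Pt")) {
  pt_isotope <- match.arg(pt_isotope)
  structure(
    list(name = name,
         bifunctional = c(Pt = 1, N = 2, H = 6),
         monofunctional = c(Pt = 1, N = 2, H = 6, Cl = 1),
         protein_reactive = protein_reactive,
         include_termini = include_termini,
         dna_reactive = dna_reactive,
         span = span, span_tol = span_tol,
         pt_isotope = pt_isotope),
    class = "pt_adduct"
  )
}

#' Mass delta of a platinum adduct mode
#'
#' @param adduct A [pt_adduct()] object.
#' @param mode `"bifunctional"` (bridging Pt(NH3)2) or `"monofunctional"`
#'   (dangling Pt(NH3)2Cl).
#' @return Mass delta in Da.
#' @export
pt_delta <- function(adduct, mode = c("bifunctional", "monofunctional")) {
  stopifnot(inherits(adduct, "pt_adduct"))
  mode <- match.arg(mode)
  formula_mass(adduct[[mode]], pt_isotope = adduct$pt_isotope)
}

# bridge mass added by a crosslinker in a given form; mono-links carry the
# hydrolyzed (bridge + water) delta
bridge_delta <- function(linker, form = c("light", "heavy", "mono_light", "mono_heavy")) {
  stopifnot(inherits(linker, "crosslinker"))
  form <- match.arg(form)
  iso <- if (form %in% c("heavy", "mono_heavy")) {
    if (is.null(linker$heavy)) {
      stop("linker '", linker$name, "' has no heavy isotope form")
    }
    linker$heavy
  } else {
    linker$light
  }
  m <- formula_mass(iso)
  if (form %in% c("mono_light", "mono_heavy")) m <- m + formula_mass(.WATER)
  m
}

#' Mass difference between heavy and light linker forms
#'
#' The characteristic isotope-doublet spacing: for d4/d0 pairs four
#' deuterium-for-hydrogen substitutions, 4.0251 Da.
#'
#' @param linker A [crosslinker()] with both isotope forms.
#' @return Heavy minus light monoisotopic mass difference in Da.
#' @examples
#' doublet_delta(xl_linkers()$DSG)
#' @export
doublet_delta <- function(linker) {
  stopifnot(inherits(linker, "crosslinker"))
  if (is.null(linker$heavy)) {
    stop("linker '", linker$name, "' has no heavy isotope form")
  }
  formula_mass(linker$heavy) - formula_mass(linker$light)
}

#' Neutral mass of a cross-linked conjugate
#'
#' Component masses plus the bridge delta of the linker form or Pt mode.
#' Additivity is exact: the result equals the sum of independently computed
#' component masses plus the bridge mass.
#'
#' @param components List of 1 or 2 components: [peptide_species()],
#'   [oligo_species()], or bare numeric masses.
#' @param bridge A [crosslinker()] or [pt_adduct()].
#' @param form For a crosslinker: `"light"`, `"heavy"`, `"mono_light"` or
#'   `"mono_heavy"`; for a Pt adduct: `"bifunctional"` or `"monofunctional"`.
#'   Mono-link / monofunctional forms require a single component.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' conjugate_mass(list(1000, 2000), pt_adduct(), "bifunctional")
#' conjugate_mass(list(500, 600), xl_linkers()$DSS, "heavy") -
#'   conjugate_mass(list(500, 600), xl_linkers()$DSS, "light") # 4.0251
#' @export
conjugate_mass <- function(components, bridge, form = "light") {
  if (!is.list(components)) components <- list(components)
  if (length(components) < 1 || length(components) > 2) {
    stop("a conjugate has 1 or 2 components, got ", length(components))
  }
  if (inherits(bridge, "pt_adduct")) {
    delta <- pt_delta(bridge, form)
    if (form == "monofunctional" && length(components) != 1) {
      stop("a monofunctional Pt adduct decorates a single component")
    }
  } else if (inherits(bridge, "crosslinker")) {
    delta <- bridge_delta(bridge, form)
    if (startsWith(form, "mono") && length(components) != 1) {
      stop("a mono-link has a single component")
    }
  } else {
    stop("bridge must be a crosslinker or pt_adduct")
  }
  sum(vapply(components, species_mass, numeric(1))) + delta
}

#' Read linker and adduct definitions from a YAML config
#'
#' The config holds a `linkers:` list (name, light/heavy compositions as
#' element: count maps, reactive classes, span, span_tol) and an optional
#' `pt_adduct:` entry (protein_reactive, dna_reactive, span, span_tol,
#' pt_isotope). See `system.file("extdata", "linkers.yaml", package =
#' "xlhdx")` for the built-in definitions in this format.
#'
#' @param path Path to a YAML file.
#' @return List with elements `linkers` (named list of [crosslinker()]) and
#'   `pt` ([pt_adduct()] or `NULL`).
#' @export
read_linker_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  linkers <- list()
  for (ln in cfg$linkers) {
    linkers[[ln$name]] <- crosslinker(
      name = ln$name,
      light = unlist(ln$light),
      heavy = if (is.null(ln$heavy)) NULL else unlist(ln$heavy),
      reactive = unlist(ln$reactive),
      span = ln$span, span_tol = ln$span_tol
    )
  }
  pt <- NULL
  if (!is.null(cfg$pt_adduct)) {
    pa <- cfg$pt_adduct
    pt <- pt_adduct(
      name = if (is.null(pa$name)) "transplatin" else pa$name,
      protein_reactive = unlist(pa$protein_reactive),
      include_termini = isTRUE(pa$include_termini),
      dna_reactive = if (is.null(pa$dna_reactive)) "G" else pa$dna_reactive,
      span = if (is.null(pa$span)) 5.0 else pa$span,
      span_tol = if (is.null(pa$span_tol)) 2.0 else pa$span_tol,
      pt_isotope = if (is.null(pa$pt_isotope)) "195Pt" else pa$pt_isotope
    )
  }
  list(linkers = linkers, pt = pt)
}
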