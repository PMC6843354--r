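#' Intact species model
#'
#' A molecular species expected in an intact-mass spectrum (free protein,
#' single strands, duplex, protein-DNA complex) with its base neutral mass
#' and the maximum number of bifunctional (tPt) and monofunctional (tPt-Cl)
#' platinum adducts to consider. Multi-adduct ladders are common, hence the
#' default of up to 5 of each.
#'
#' @param name Species label (e.g. `"dsDBD"`, `"ssDBD-F"`).
#' @param base_mass Neutral monoisotopic mass of the unmodified species (Da).
#' @param max_bifunctional,max_monofunctional Maximum adduct counts.
#' @return A list of class `species_model`.
#' @export
species_model <- function(name, base_mass, max_bifunctional = 5L,
                          max_monofunctional = 5L) {
  stopifnot(base_mass > 0, max_bifunctional >= 0, max_monofunctional >= 0)
  structure(
    list(name = name, base_mass = base_mass,
         max_bifunctional = as.integer(max_bifunctional),
         max_monofunctional = as.integer(max_monofunctional)),
    class = "species_model"
  )
}

#' Annotate deconvoluted intact masses with Pt adduct ladders
#'
#' For every observed neutral mass, enumerates all (species, n, m)
#' combinations whose theoretical mass `base + n * delta(tPt) + m *
#' delta(tPt-Cl)` falls within the ppm tolerance. Ambiguous peaks retain all
#' candidate assignments, ranked by absolute ppm error; no winner-takes-all
#' call is made.
#'
#' @param peaks Data frame with columns `mass` and (optionally) `intensity`.
#' @param species List of [species_model()] objects.
#' @param adduct A [pt_adduct()] giving the tPt / tPt-Cl mass deltas.
#' @param ppm_tol Match tolerance in ppm (> 0).
#' @return Data frame with columns `observed`, `species`, `n_bifunctional`,
#'   `m_monofunctional`, `theoretical`, `ppm`, sorted by observed mass then
#'   absolute ppm.
#' @export
annotate_intact <- function(peaks, species, adduct = pt_adduct(), ppm_tol = 5) {
  if (length(species) == 0) stop("species list must be non-empty")
  if (inherits(species, "species_model")) species <- list(species)
  stopifnot(ppm_tol > 0, all(peaks$mass > 0))
  d_bi <- pt_delta(adduct, "bifunctional")
  d_mono <- pt_delta(adduct, "monofunctional")
  grid <- do.call(rbind, lapply(species, function(sp) {
    g <- expand.grid(n = 0:sp$max_bifunctional, m = 0:sp$max_monofunctional)
    data.frame(species = sp$name, n = g$n, m = g$m,
               theoretical = sp$base_mass + g$n * d_bi + g$m * d_mono,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$mass[i]
    ppm <- (obs - grid$theoretical) / grid$theoretical * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (length(hit) == 0) next
    o <- data.frame(observed = obs, species = grid$species[hit],
                    n_bifunctional = grid$n[hit], m_monofunctional = grid$m[hit],
                    theoretical = grid$theoretical[hit], ppm = ppm[hit],
                    stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- o[order(abs(o$ppm)), , drop = FALSE]
  }
  if (length(out) == 0) {
    return(data.frame(observed = numeric(0), species = character(0),
                      n_bifunctional = integer(0), m_monofunctional = integer(0),
                      theoretical = numeric(0), ppm = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify complexes as bridged or non-bridged from paired conditions
#'
#' Applies the denaturing-condition test: a complex whose signal survives
#' mild denaturation must be held together by covalent bifunctional bridges;
#' a complex seen only natively, whose free components appear under
#' denaturation, is non-covalent. Species absent from both sets are
#' unclassified.
#'
#' @param native,denatured Annotation tables from [annotate_intact()] for
#'   the same sample under native and denaturing conditions.
#' @param complexes Named list: complex species name -> character vector of
#'   its free component species names.
#' @return Data frame with columns `complex` and `classification`
#'   (`"bridged"`, `"non-bridged"`, `"unclassified"`).
#' @export
bridged_species_test <- function(native, denatured, complexes) {
  cls <- vapply(names(complexes), function(cx) {
    in_nat <- cx %in% native$species
    in_den <- cx %in% denatured$species
    if (in_den) return("bridged")
    comps_free <- all(complexes[[cx]] %in% denatured$species)
    if (in_nat && comps_free) return("non-bridged")
    "unclassified"
  }, character(1))
  data.frame(complex = names(complexes), classification = unname(cls),
             stringsAsFactors = FALSE)
}

#' Read a deconvoluted peak list
#'
#' @param path CSV file with columns `mass` and `intensity`.
#' @return Data frame with numeric `mass` and `intensity`.
#' @export
read_peaklist <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mass" %in% names(tab)) stop("peak list must have a 'mass' column: ", path)
  if (!"intensity" %in% names(tab)) tab$intensity <- 1
  tab[, c("mass", "intensity")]
}

#' Write a peak list CSV
#' @param peaks Data frame with `mass` and `intensity`.
#' @param path Output path.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.csv(peaks[, c("mass", "intensity")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
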