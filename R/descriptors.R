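#' Frontier-orbital energy pair
#'
#' @param e_homo,e_lumo HOMO and LUMO energies \[eV\]; `e_lumo > e_homo`.
#' @param label Species name.
#' @return Object of class `orbital_energies`.
#' @export
orbital_energies <- function(e_homo, e_lumo, label = "") {
  if (!.is_number(e_homo) || !.is_number(e_lumo))
    .stop_ampchem("orbital energies must be finite scalars",
                  "ampchem_invalid_parameter")
  if (e_lumo <= e_homo)
    .stop_ampchem("e_lumo must exceed e_homo", "ampchem_ordering_error")
  structure(list(e_homo = e_homo, e_lumo = e_lumo, label = label),
            class = "orbital_energies")
}

#' HSAB reactivity descriptors from frontier-orbital energies
#'
#' Computes the HOMO-LUMO gap `dE = E_LUMO - E_HOMO` (positive convention),
#' the chemical hardness `eta = dE / 2`, and the electronegativity
#' `chi = |E_LUMO + E_HOMO| / 2`. The electronegativity is reported in the
#' magnitude convention (the raw half-sum is negative for bound orbitals);
#' the signed value is retained in `chi_signed`.
#'
#' @param orb An [orbital_energies()] object.
#' @return Object of class `descriptor_set`: `gap`, `hardness`,
#'   `electronegativity` \[eV\], `chi_signed` and `label`. The identity
#'   `gap == 2 * hardness` holds exactly.
#' @examples
#' compute_descriptors(orbital_energies(-7.4133, -0.6579, "DPPC"))
#' @export
compute_descriptors <- function(orb) {
  stopifnot(inherits(orb, "orbital_energies"))
  gap <- orb$e_lumo - orb$e_homo
  chi_raw <- (orb$e_lumo + orb$e_homo) / 2
  structure(list(gap = gap, hardness = gap / 2,
                 electronegativity = abs(chi_raw), chi_signed = chi_raw,
                 label = orb$label),
            class = "descriptor_set")
}

#' Interaction energy of a complex
#'
#' `E_int = E_complex - (E_partner + E_ligand)`; negative values indicate
#' favourable affinity between the partners (e.g. a phospholipid and a
#' surfactant forming a mixed aggregate).
#'
#' @param e_complex Total energy of the complex \[eV\].
#' @param e_partner,e_ligand Total energies of the isolated partners \[eV\];
#'   their order does not matter.
#' @return Interaction energy \[eV\].
#' @examples
#' interaction_energy(-100, -60, -39.4558)  # -0.5442
#' @export
interaction_energy <- function(e_complex, e_partner, e_ligand) {
  if (!all(vapply(list(e_complex, e_partner, e_ligand), .is_number,
                  logical(1))))
    .stop_ampchem("energies must be finite scalars",
                  "ampchem_invalid_parameter")
  e_complex - (e_partner + e_ligand)
}

#' Rank complexes by interaction affinity
#'
#' Orders species by ascending interaction energy, i.e. strongest to weakest
#' affinity; ties keep their input order (stable sort).
#'
#' @param e_int Numeric vector of interaction energies \[eV\].
#' @param labels Species labels, same length.
#' @return Data frame with `label` and `e_int`, strongest affinity first.
#' @export
rank_affinity <- function(e_int, labels) {
  if (length(e_int) < 2L || length(labels) != length(e_int))
    .stop_ampchem("need >= 2 labelled energies", "ampchem_invalid_parameter")
  ord <- order(e_int)  # stable in R
  data.frame(label = labels[ord], e_int = e_int[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hartree to electron-volt conversion
#'
#' @param x Energies in Hartree.
#' @return Energies in eV (`x * 27.211386`).
#' @export
hartree_to_ev <- function(x) x * 27.211386
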