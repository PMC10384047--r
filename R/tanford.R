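#' Tanford volume of a saturated hydrocarbon chain
#'
#' Empirical group-additive volume of a terminal methyl plus `n` methylene
#' groups: `v = 0.0274 + 0.0269 * n` nm^3.
#'
#' @param n_formula_carbons Number of methylene carbons entering the formula.
#'   For the acyl surfactants handled here the convention is tail carbons
#'   minus one (the carbonyl-adjacent carbon is counted with the headgroup),
#'   so a dodecanoyl (C12) tail uses n = 10 in the length formula and n = 11
#'   in the volume formula depending on the group split; see
#'   [surfactant_spec()].
#' @return Chain volume \[nm^3\].
#' @examples
#' tanford_chain_volume(11)  # 0.3233 nm^3
#' @export
tanford_chain_volume <- function(n_formula_carbons) {
  if (any(!is.finite(n_formula_carbons)) || any(n_formula_carbons < 0))
    .stop_ampchem("carbon count must be >= 0", "ampchem_invalid_parameter")
  0.0274 + 0.0269 * n_formula_carbons
}

#' Tanford maximum extended chain length
#'
#' `l_max = 0.154 + 0.1265 * n` nm for a chain of `n` methylene carbons plus
#' the terminal methyl. With the tail-carbons-minus-one convention this gives
#' 1.4 nm for dodecanoyl (n = 10) and 1.7 nm for tetradecanoyl (n = 12)
#' tails after rounding to one decimal.
#'
#' @inheritParams tanford_chain_volume
#' @return Maximum extended length \[nm\].
#' @examples
#' round(tanford_max_length(10), 1)  # 1.4
#' round(tanford_max_length(12), 1)  # 1.7
#' @export
tanford_max_length <- function(n_formula_carbons) {
  if (any(!is.finite(n_formula_carbons)) || any(n_formula_carbons < 0))
    .stop_ampchem("carbon count must be >= 0", "ampchem_invalid_parameter")
  0.154 + 0.1265 * n_formula_carbons
}

#' Surfactant chemical specification
#'
#' Bundles the per-molecule quantities needed to turn fitted micelle geometry
#' into derived structural numbers (aggregation number, hydration, area per
#' molecule) and to compute the hydrocarbon volume fraction of a solution.
#'
#' @param n_tail_carbons Carbons in the acyl tail (12 for dodecanoyl
#'   homologs, 14 for tetradecanoyl).
#' @param n_formula_carbons Carbon count fed to the Tanford formulas;
#'   defaults to `n_tail_carbons - 1` (the carbonyl-adjacent carbon is
#'   assigned to the headgroup region).
#' @param head_electrons Electrons in the (dry) polar headgroup.
#' @param head_dry_volume Dry headgroup volume \[nm^3\].
#' @param molar_mass Molar mass \[g/mol\].
#' @param concentration Solution concentration \[mM\].
#' @return An object of class `surfactant_spec`.
#' @export
surfactant_spec <- function(n_tail_carbons, n_formula_carbons = n_tail_carbons - 1L,
                            head_electrons = 150, head_dry_volume = 0.35,
                            molar_mass = NA_real_, concentration = 10) {
  if (!.is_number(n_tail_carbons) || n_tail_carbons < 6)
    .stop_ampchem("n_tail_carbons must be >= 6", "ampchem_invalid_parameter")
  if (!.is_number(head_dry_volume) || head_dry_volume <= 0)
    .stop_ampchem("head_dry_volume must be > 0", "ampchem_invalid_parameter")
  if (!.is_number(concentration) || concentration <= 0)
    .stop_ampchem("concentration must be > 0", "ampchem_invalid_parameter")
  structure(list(n_tail_carbons = as.integer(n_tail_carbons),
                 n_formula_carbons = as.integer(n_formula_carbons),
                 head_electrons = head_electrons,
                 head_dry_volume = head_dry_volume,
                 molar_mass = molar_mass,
                 concentration = concentration),
            class = "surfactant_spec")
}

#' Hydrocarbon volume fraction of a surfactant solution
#'
#' `phi = c * N_A * v_chain`, with the concentration converted to mol/L and
#' the Tanford chain volume to litres. Linear in concentration.
#'
#' @param spec A [surfactant_spec()].
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(spec) {
  stopifnot(inherits(spec, "surfactant_spec"))
  v_chain_l <- tanford_chain_volume(spec$n_formula_carbons) * 1e-24  # nm^3 -> L
  (spec$concentration * 1e-3) * 6.02214076e23 * v_chain_l
}
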