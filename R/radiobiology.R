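# Dose corrections applied before risk modelling: radiation weighting
# (Gy -> Sv), uniform stray-dose addition, and per-bin linear-quadratic
# correction to a 2 Gy-per-fraction schedule (EQD2).

#' Fractionation scheme
#'
#' Bundles the number of fractions, the tissue alpha/beta ratio, and the
#' reference dose per fraction of the EQD2 schedule. The cardiac late-effect
#' default is alpha/beta = 3 Gy; the mediastinal plan uses 18 fractions and
#' the craniospinal plan 13.
#'
#' @param n_fractions Number of treatment fractions (>= 1).
#' @param alpha_beta Linear-quadratic alpha/beta ratio in Gy (> 0).
#' @param reference_dose_per_fraction Reference fraction dose of the
#'   equivalent schedule, Gy; 2 Gy by convention.
#' @return An object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(n_fractions, alpha_beta = 3,
                                 reference_dose_per_fraction = 2) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer")
  if (alpha_beta <= 0) stop("`alpha_beta` must be positive")
  if (reference_dose_per_fraction <= 0)
    stop("`reference_dose_per_fraction` must be positive")
  out <- list(n_fractions = n_fractions, alpha_beta = alpha_beta,
              reference_dose_per_fraction = reference_dose_per_fraction)
  class(out) <- "fractionation_scheme"
  out
}

#' Radiation weighting factors
#'
#' Multipliers converting mean absorbed dose (Gy) to equivalent dose (Sv):
#' 1.1 for the primary proton field (i.e. doses reported in Gy (RBE)), 1.0
#' for photon fields, and a patient-specific value of order 10 for stray
#' neutrons. `neutron_scale` is an extra multiplier on the stray neutron
#' term used by the weighting-factor sensitivity sweep; it is unrestricted
#' here even though the sweeps explore [0.5, 10].
#'
#' @param wr_proton_primary Weighting factor for the primary proton field.
#' @param wr_photon Weighting factor for photon fields.
#' @param wr_neutron Mean neutron weighting factor (configuration input).
#' @param neutron_scale Dimensionless multiplier on the stray neutron
#'   equivalent dose, default 1.
#' @return An object of class `weighting_factors`.
#' @export
weighting_factors <- function(wr_proton_primary = 1.1, wr_photon = 1.0,
                              wr_neutron = 8.5, neutron_scale = 1) {
  vals <- c(wr_proton_primary, wr_photon, wr_neutron, neutron_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all weighting factors must be positive and finite")
  out <- list(wr_proton_primary = wr_proton_primary, wr_photon = wr_photon,
              wr_neutron = wr_neutron, neutron_scale = neutron_scale)
  class(out) <- "weighting_factors"
  out
}

#' Equivalent dose from absorbed dose
#'
#' `H_T = wR * D_T`: multiplies a mean organ absorbed dose by a radiation
#' weighting factor.
#'
#' @param organ_dose Mean absorbed organ dose, Gy (>= 0). Vectorized.
#' @param wr Radiation weighting factor (> 0).
#' @return Equivalent dose in Sv.
#' @export
equivalent_dose <- function(organ_dose, wr) {
  if (any(organ_dose < 0)) stop("`organ_dose` must be non-negative")
  if (any(wr <= 0)) stop("`wr` must be positive")
  wr * organ_dose
}

#' Total mean equivalent dose from primary and stray components
#'
#' The bookkeeping behind the proton "Total" dose column:
#' `wr_primary * primary + neutron_scale * stray_equivalent`. The stray term
#' is already an equivalent dose (neutron absorbed dose times neutron wR);
#' `neutron_scale` rescales it for sensitivity analysis.
#'
#' @param primary Mean primary absorbed dose, Gy (>= 0). Vectorized.
#' @param wr_primary Primary-field weighting factor.
#' @param stray_equivalent Mean stray equivalent dose, Sv (>= 0).
#' @param neutron_scale Multiplier on the stray term, default 1.
#' @return Total mean equivalent dose, Sv.
#' @examples
#' total_mean_equivalent_dose(8.90, 1.1, 0.66)  # 10.45 Sv
#' @export
total_mean_equivalent_dose <- function(primary, wr_primary, stray_equivalent,
                                       neutron_scale = 1) {
  if (any(primary < 0) || any(stray_equivalent < 0))
    stop("doses must be non-negative")
  if (any(neutron_scale < 0)) stop("`neutron_scale` must be non-negative")
  equivalent_dose(primary, wr_primary) + neutron_scale * stray_equivalent
}

#' Weight a DVH's dose axis into equivalent dose
#'
#' Multiplies every bin dose (and the bin width) by a radiation weighting
#' factor and relabels the unit Sv. Identity weighting (`wr = 1`) still
#' relabels, recording that subsequent arithmetic is on the equivalent-dose
#' scale.
#'
#' @param dvh A `dvh_differential` object.
#' @param wr Radiation weighting factor (> 0).
#' @return A `dvh_differential` in Sv.
#' @export
weight_dvh <- function(dvh, wr) {
  stopifnot(inherits(dvh, "dvh_differential"))
  if (wr <= 0) stop("`wr` must be positive")
  dvh_differential(dvh$dose * wr, dvh$volume, dvh$structure, "Sv",
                   bin_width = dvh$bin_width * wr)
}

#' Add a spatially uniform equivalent dose to a DVH
#'
#' Shifts every bin center up by `shift`, leaving volumes untouched, so the
#' mean dose increases by exactly `shift`. This is how a spatially
#' near-uniform stray neutron bath is folded into a primary proton DVH. The
#' DVH must already be on the equivalent-dose (Sv) scale.
#'
#' @param dvh A `dvh_differential` in Sv.
#' @param shift Uniform equivalent dose to add, Sv (>= 0).
#' @return The shifted `dvh_differential`.
#' @export
add_uniform_dose <- function(dvh, shift) {
  stopifnot(inherits(dvh, "dvh_differential"))
  if (!identical(dvh$unit, "Sv"))
    stop("uniform equivalent-dose addition requires a DVH in Sv; ",
         "apply weight_dvh() first")
  if (shift < 0) stop("`shift` must be non-negative")
  if (shift == 0) return(dvh)
  dvh_differential(dvh$dose + shift, dvh$volume, dvh$structure, dvh$unit,
                   bin_width = dvh$bin_width)
}

#' Scalar EQD2 correction
#'
#' Maps a total dose `D` delivered in `n` fractions to the biologically
#' equivalent total dose at the reference fraction size (2 Gy):
#' `D * (d + alpha/beta) / (d_ref + alpha/beta)` with per-fraction dose
#' `d = D / n`. Identity exactly when `d` equals the reference fraction
#' dose.
#'
#' @param dose Total dose (vectorized, >= 0).
#' @param scheme A [fractionation_scheme()].
#' @return EQD2-corrected dose.
#' @export
eqd2 <- function(dose, scheme) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (any(dose < 0)) stop("`dose` must be non-negative")
  d <- dose / scheme$n_fractions
  dose * (d + scheme$alpha_beta) /
    (scheme$reference_dose_per_fraction + scheme$alpha_beta)
}

#' Per-bin EQD2 correction of a differential DVH
#'
#' Applies [eqd2()] to every bin-center dose, with each bin's dose assumed
#' to be delivered evenly over all fractions (per-bin fraction dose
#' `D_i / n`). Volumes are unchanged. The map is strictly monotone in dose,
#' so bin ordering is preserved, but it is non-linear, so the output grid is
#' no longer uniform and `bin_width` becomes `NA`.
#'
#' @param dvh A `dvh_differential` object.
#' @param scheme A [fractionation_scheme()].
#' @return The corrected `dvh_differential`.
#' @export
eqd2_correct <- function(dvh, scheme) {
  stopifnot(inherits(dvh, "dvh_differential"))
  validate_dvh(dvh)
  dvh_differential(eqd2(dvh$dose, scheme), dvh$volume, dvh$structure,
                   dvh$unit, bin_width = NA_real_)
}
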