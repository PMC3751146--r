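# Bundled model parameters and published mean-dose inputs for the two
# reference cases: a mediastinal Hodgkin-disease (HD) plan and a
# craniospinal medulloblastoma (MB) plan, each planned with both photons
# and passively scattered protons.

#' Published NTCP parameter sets for cardiac structures
#'
#' Literature parameter sets for cardiac complication models: Lyman sets
#' (`td50`/`n_vol`/`m`) for the pericardium and relative-seriality sets
#' (`d50`/`gamma`/`s`) for the myocardium and whole heart. Sources span
#' Hodgkin-disease, breast-cancer, esophageal-cancer, and pooled historical
#' outcome data; only the Hodgkin-derived sets (`hd_applicable`) are used
#' for absolute NTCP reporting in the HD case, while all sets are run for
#' ratio-only reporting in the MB case.
#'
#' @return A data frame with one row per parameter set: `structure`,
#'   `source`, `set_id`, `model` (`"lyman"` or `"rs"`), `d50` (Gy; the
#'   Lyman rows store `TD50(1)` here), `n_vol`, `m`, `gamma`, `s`,
#'   `hd_applicable`.
#' @export
cardiac_param_sets <- function() {
  data.frame(
    structure = c("pericardium", "pericardium", "myocardium", "myocardium",
                  "whole_heart", "whole_heart", "whole_heart"),
    source = c("pooled_historical", "esophageal", "breast", "hodgkin",
               "breast", "hodgkin", "hodgkin"),
    set_id = c("pericardium_lyman_48", "pericardium_lyman_50.6",
               "myocardium_rs_52.2", "myocardium_rs_70.3",
               "whole_heart_rs_52.3", "whole_heart_rs_63.3",
               "whole_heart_rs_70.3"),
    model = c("lyman", "lyman", "rs", "rs", "rs", "rs", "rs"),
    d50 = c(48, 50.6, 52.2, 70.3, 52.3, 63.3, 70.3),
    n_vol = c(0.35, 0.64, NA, NA, NA, NA, NA),
    m = c(0.1, 0.13, NA, NA, NA, NA, NA),
    gamma = c(NA, NA, 1.25, 0.96, 1.28, 0.93, 0.96),
    s = c(NA, NA, 0.87, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  ) |> within(hd_applicable <- source == "hodgkin")
}

# Build the model-parameter object for one row of cardiac_param_sets().
.param_set_object <- function(row) {
  if (identical(row$model, "rs")) rs_params(row$d50, row$gamma, row$s)
  else lyman_params(row$d50, row$n_vol, row$m)
}

#' Published mean organ doses for the HD and MB reference plans
#'
#' Mean absorbed and equivalent doses to the pericardium, myocardium and
#' whole heart for each patient and modality, as published: proton primary
#' absorbed dose (Gy), stray neutron absorbed dose (Gy), their
#' equivalent-dose counterparts (Sv; primary weighted by wR = 1.1), the
#' published proton total (Sv, rounded to 2 decimals in the source table),
#' and the photon mean dose (Gy, numerically equal in Sv since photon
#' wR = 1). `wr_neutron` is the neutron weighting factor reconstructed as
#' the ratio of the published stray equivalent to stray absorbed dose; the
#' underlying Monte Carlo values were not published, so these are
#' informational, not authoritative.
#'
#' @return A data frame with one row per patient/structure.
#' @export
cardiac_dose_table <- function() {
  tab <- data.frame(
    patient = rep(c("MB", "HD"), each = 3),
    structure = rep(c("pericardium", "myocardium", "whole_heart"), 2),
    primary_gy = c(0.55, 0.13, 0.19, 11.15, 9.05, 8.90),
    stray_gy = c(0.032, 0.033, 0.032, 0.081, 0.077, 0.078),
    primary_sv = c(0.61, 0.14, 0.21, 12.27, 9.95, 9.79),
    stray_sv = c(0.26, 0.26, 0.26, 0.69, 0.65, 0.66),
    total_sv = c(0.87, 0.40, 0.47, 12.96, 10.60, 10.45),
    photon_gy = c(10.59, 11.72, 12.31, 14.26, 12.23, 12.28),
    stringsAsFactors = FALSE
  )
  tab$wr_neutron <- tab$stray_sv / tab$stray_gy
  tab
}

#' Fraction counts of the reference plans
#'
#' 18 fractions for the mediastinal HD plans (36 Gy (RBE) / 36 Gy
#' prescribed), 13 for the craniospinal MB plans (23.4 Gy (RBE) / 23.4 Gy).
#'
#' @param patient `"HD"` or `"MB"`.
#' @return A [fractionation_scheme()] with alpha/beta = 3 Gy.
#' @export
reference_fractionation <- function(patient = c("HD", "MB")) {
  patient <- match.arg(patient)
  fractionation_scheme(if (patient == "HD") 18L else 13L, alpha_beta = 3)
}
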