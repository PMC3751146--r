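# Patient-level comparison pipeline: assemble mean doses and DVHs into
# relative risks, NTCP values, and the proton/photon ratios RRR and RNTCP,
# per structure and parameter set.

#' Assemble a comparison case
#'
#' A case bundles everything needed to compare a proton and a photon plan
#' for one patient: the mean-dose table, optional DVHs per structure and
#' modality, the fractionation scheme, and the radiation weighting factors.
#'
#' @param patient Case label, e.g. `"HD"` or `"MB"`.
#' @param dose_table Data frame with one row per structure and columns
#'   `structure`, `primary_gy` (proton primary mean absorbed dose),
#'   `stray_gy` (stray neutron mean absorbed dose), `stray_sv` (stray mean
#'   equivalent dose), `photon_gy` (photon mean dose); an optional
#'   `total_sv` column may carry a published proton total equivalent dose.
#' @param dvhs Named list: `dvhs[[structure]]$proton` /
#'   `dvhs[[structure]]$photon`, each a `dvh_differential`. Proton DVHs are
#'   expected in Sv (RBE-weighted primary dose); photon DVHs in Gy. May be
#'   empty, in which case only mean-dose quantities are computable.
#' @param fractionation A [fractionation_scheme()].
#' @param weighting A [weighting_factors()].
#' @return An object of class `cardrisk_case`.
#' @export
cardrisk_case <- function(patient, dose_table, dvhs = list(),
                          fractionation, weighting = weighting_factors()) {
  stopifnot(inherits(fractionation, "fractionation_scheme"),
            inherits(weighting, "weighting_factors"))
  needed <- c("structure", "primary_gy", "stray_gy", "stray_sv", "photon_gy")
  missing_cols <- setdiff(needed, names(dose_table))
  if (length(missing_cols))
    stop("dose_table lacks columns: ", paste(missing_cols, collapse = ", "))
  num <- unlist(dose_table[setdiff(needed, "structure")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("dose_table doses must be finite and non-negative")
  if (anyDuplicated(dose_table$structure))
    stop("dose_table structures must be unique")
  # published stray equivalent must be consistent with absorbed x wR when
  # a neutron weighting factor accompanies the table
  if (!is.null(dose_table$wr_neutron)) {
    recomputed <- dose_table$stray_gy * dose_table$wr_neutron
    if (any(abs(recomputed - dose_table$stray_sv) > 0.005 + 1e-9))
      stop("stray_sv inconsistent with stray_gy * wr_neutron")
  }
  bad <- setdiff(names(dvhs), dose_table$structure)
  if (length(bad))
    stop("DVHs supplied for structures absent from dose_table: ",
         paste(bad, collapse = ", "))
  for (st in names(dvhs)) {
    for (mod in names(dvhs[[st]])) {
      if (!mod %in% c("proton", "photon"))
        stop("unknown modality '", mod, "' for structure ", st)
      if (!inherits(dvhs[[st]][[mod]], "dvh_differential"))
        stop("DVH for ", st, "/", mod, " is not a differential DVH")
      validate_dvh(dvhs[[st]][[mod]])
    }
  }
  out <- list(patient = as.character(patient)[1], dose_table = dose_table,
              dvhs = dvhs, fractionation = fractionation,
              weighting = weighting)
  class(out) <- "cardrisk_case"
  out
}

#' @export
print.cardrisk_case <- function(x, ...) {
  cat(sprintf("cardrisk case '%s': %d structures, DVHs for {%s}, %d fractions\n",
              x$patient, nrow(x$dose_table),
              paste(names(x$dvhs), collapse = ", "),
              x$fractionation$n_fractions))
  invisible(x)
}

#' Ratio of relative risks between modalities
#'
#' `RRR = RR_proton / RR_photon`. Reports are rounded to 2 decimals; the
#' returned value is full precision.
#'
#' @param rr_proton,rr_photon Relative risks (vectorized); `rr_photon` must
#'   be positive (it is always >= 1 for non-negative dose).
#' @return The ratio.
#' @export
compute_rrr <- function(rr_proton, rr_photon) {
  if (any(rr_photon <= 0)) stop("`rr_photon` must be positive")
  rr_proton / rr_photon
}

#' Ratio of NTCP values between modalities
#'
#' `RNTCP = NTCP_proton / NTCP_photon`, with explicit handling of the
#' numerically-zero regime: if both probabilities fall below `eps` the
#' ratio is reported as 0 with flag `"both_zero"` (matching the published
#' convention of reporting 0 for vanishing pericardium NTCP); if only the
#' photon NTCP vanishes there is no finite ratio and the flag is
#' `"photon_zero"` with value `Inf`.
#'
#' @param ntcp_proton,ntcp_photon Probabilities in \[0, 1\] (vectorized).
#' @param eps Zero threshold on the probability scale, default `1e-12`.
#' @return A data frame with columns `rntcp` and `flag`
#'   (`"ok"`, `"both_zero"`, or `"photon_zero"`).
#' @export
compute_rntcp <- function(ntcp_proton, ntcp_photon, eps = 1e-12) {
  if (any(ntcp_proton < 0 | ntcp_proton > 1) ||
      any(ntcp_photon < 0 | ntcp_photon > 1))
    stop("NTCP inputs must lie in [0, 1]")
  n <- max(length(ntcp_proton), length(ntcp_photon))
  p <- rep_len(ntcp_proton, n)
  q <- rep_len(ntcp_photon, n)
  flag <- ifelse(p < eps & q < eps, "both_zero",
                 ifelse(q < eps, "photon_zero", "ok"))
  val <- ifelse(flag == "both_zero", 0,
                ifelse(flag == "photon_zero", Inf, p / q))
  data.frame(rntcp = val, flag = flag, stringsAsFactors = FALSE)
}

#' Process a structure's DVH onto the EQD2 equivalent-dose scale
#'
#' The per-modality preprocessing applied before any NTCP evaluation:
#' proton DVHs (RBE-weighted primary dose; a Gy-labelled proton DVH is
#' first weighted by `wr_proton_primary`) receive the uniform stray neutron
#' equivalent-dose shift (`neutron_scale * stray_sv`), then the per-bin
#' EQD2 correction; photon DVHs are weighted by `wr_photon` (relabelling to
#' Sv) and EQD2-corrected, their stray dose being already contained in the
#' planning-system DVH.
#'
#' @param case A [cardrisk_case()].
#' @param structure Structure name present in `case$dvhs`.
#' @param modality `"proton"` or `"photon"`.
#' @param neutron_scale Multiplier on the stray equivalent dose; defaults
#'   to the case's weighting factors.
#' @return A `dvh_differential` in Sv on the EQD2 scale.
#' @export
prepare_equivalent_dvh <- function(case, structure,
                                   modality = c("proton", "photon"),
                                   neutron_scale = NULL) {
  stopifnot(inherits(case, "cardrisk_case"))
  modality <- match.arg(modality)
  dvh <- case$dvhs[[structure]][[modality]]
  if (is.null(dvh))
    stop("no ", modality, " DVH for structure '", structure, "' in this case")
  wf <- case$weighting
  if (is.null(neutron_scale)) neutron_scale <- wf$neutron_scale
  if (modality == "proton") {
    if (identical(dvh$unit, "Gy")) dvh <- weight_dvh(dvh, wf$wr_proton_primary)
    row <- case$dose_table[case$dose_table$structure == structure, ]
    dvh <- add_uniform_dose(dvh, neutron_scale * row$stray_sv)
  } else {
    if (identical(dvh$unit, "Gy")) dvh <- weight_dvh(dvh, wf$wr_photon)
  }
  eqd2_correct(dvh, case$fractionation)
}

# Total mean equivalent doses per structure for each modality.
.case_mean_doses <- function(case, neutron_scale = NULL,
                             total_from = c("components", "table")) {
  total_from <- match.arg(total_from)
  wf <- case$weighting
  if (is.null(neutron_scale)) neutron_scale <- wf$neutron_scale
  tab <- case$dose_table
  if (total_from == "table") {
    if (is.null(tab$total_sv))
      stop("dose_table carries no published total_sv column")
    if (neutron_scale != 1)
      stop("published totals are only valid at neutron_scale = 1")
    d_proton <- tab$total_sv
  } else {
    d_proton <- total_mean_equivalent_dose(tab$primary_gy,
                                           wf$wr_proton_primary,
                                           tab$stray_sv, neutron_scale)
  }
  list(proton = d_proton, photon = equivalent_dose(tab$photon_gy, wf$wr_photon))
}

#' Run the full comparison pipeline on a case
#'
#' Computes, per structure: the linear-model relative risks for both
#' modalities (from the total mean equivalent dose for protons and the
#' weighted mean dose for photons) with confidence bounds and their ratio
#' RRR; and, for every applicable NTCP parameter set and every structure
#' with DVHs for both modalities, the proton and photon NTCP values (DVHs
#' processed via [prepare_equivalent_dvh()]) and their ratio RNTCP.
#' Absolute NTCP values are flagged for reporting only when the parameter
#' set was derived from the same disease cohort as the case
#' (`hd_applicable` sets for an HD case); ratios are always reported.
#'
#' @param case A [cardrisk_case()].
#' @param param_sets Data frame in the layout of [cardiac_param_sets()];
#'   rows are matched to structures by name.
#' @param neutron_scale Override of the case's stray-dose multiplier.
#' @param eps Zero threshold passed to [compute_rntcp()].
#' @param risk_params A [linear_risk_params()] object.
#' @param total_from `"components"` (default) recomputes the proton total
#'   equivalent dose as `wr_primary * primary + neutron_scale * stray`;
#'   `"table"` uses a published `total_sv` column as-is.
#' @param reduction Lyman DVH reduction, see [ntcp_lyman_dvh()].
#' @return An object of class `cardrisk_result`: a list with elements
#'   `patient`, `rr` (per-structure relative-risk table) and `ntcp`
#'   (per-structure, per-parameter-set NTCP table; zero rows if the case
#'   has no DVHs).
#' @export
run_case <- function(case, param_sets = cardiac_param_sets(),
                     neutron_scale = NULL, eps = 1e-12,
                     risk_params = linear_risk_params(),
                     total_from = c("components", "table"),
                     reduction = c("effective_volume", "geud")) {
  stopifnot(inherits(case, "cardrisk_case"))
  total_from <- match.arg(total_from)
  reduction <- match.arg(reduction)
  tab <- case$dose_table
  doses <- .case_mean_doses(case, neutron_scale, total_from)
  rr_p <- relative_risk(doses$proton, risk_params)
  rr_q <- relative_risk(doses$photon, risk_params)
  rr <- data.frame(structure = tab$structure,
                   d_proton_sv = doses$proton, d_photon_sv = doses$photon,
                   rr_proton = rr_p$rr, rr_proton_lower = rr_p$rr_lower,
                   rr_proton_upper = rr_p$rr_upper,
                   rr_photon = rr_q$rr, rr_photon_lower = rr_q$rr_lower,
                   rr_photon_upper = rr_q$rr_upper,
                   rrr = compute_rrr(rr_p$rr, rr_q$rr),
                   stringsAsFactors = FALSE)

  ntcp_rows <- list()
  for (st in names(case$dvhs)) {
    if (is.null(case$dvhs[[st]]$proton) || is.null(case$dvhs[[st]]$photon))
      next
    sets <- param_sets[param_sets$structure == st, , drop = FALSE]
    if (!nrow(sets)) next
    dvh_p <- prepare_equivalent_dvh(case, st, "proton", neutron_scale)
    dvh_q <- prepare_equivalent_dvh(case, st, "photon", neutron_scale)
    for (i in seq_len(nrow(sets))) {
      row <- sets[i, ]
      pars <- .param_set_object(row)
      if (identical(row$model, "rs")) {
        np <- ntcp_relative_seriality(dvh_p, pars)
        nq <- ntcp_relative_seriality(dvh_q, pars)
      } else {
        np <- ntcp_lyman_dvh(dvh_p, pars, reduction)
        nq <- ntcp_lyman_dvh(dvh_q, pars, reduction)
      }
      rat <- compute_rntcp(np, nq, eps)
      ntcp_rows[[length(ntcp_rows) + 1L]] <- data.frame(
        structure = st, set_id = row$set_id, model = row$model,
        source = row$source,
        ntcp_proton = np, ntcp_photon = nq,
        rntcp = rat$rntcp, flag = rat$flag,
        report_absolute = isTRUE(row$hd_applicable) &&
          identical(case$patient, "HD"),
        stringsAsFactors = FALSE)
    }
  }
  ntcp <- if (length(ntcp_rows)) do.call(rbind, ntcp_rows) else
    data.frame(structure = character(), set_id = character(),
               model = character(), source = character(),
               ntcp_proton = numeric(), ntcp_photon = numeric(),
               rntcp = numeric(), flag = character(),
               report_absolute = logical(), stringsAsFactors = FALSE)
  out <- list(patient = case$patient, rr = rr, ntcp = ntcp)
  class(out) <- "cardrisk_result"
  out
}

#' @export
print.cardrisk_result <- function(x, ...) {
  cat(sprintf("Cardiac toxicity comparison, case '%s'\n\n", x$patient))
  rr <- x$rr
  cat("Relative risk (linear model, mean equivalent dose):\n")
  hum <- data.frame(structure = rr$structure,
                    RR_proton = sprintf("%.2f (%.2f-%.2f)", rr$rr_proton,
                                        rr$rr_proton_lower, rr$rr_proton_upper),
                    RR_photon = sprintf("%.2f (%.2f-%.2f)", rr$rr_photon,
                                        rr$rr_photon_lower, rr$rr_photon_upper),
                    RRR = sprintf("%.2f", rr$rrr))
  print(hum, row.names = FALSE)
  if (nrow(x$ntcp)) {
    cat("\nNTCP (per parameter set):\n")
    nt <- x$ntcp
    hum2 <- data.frame(structure = nt$structure, set = nt$set_id,
                       NTCP_proton = ifelse(nt$report_absolute,
                                            sprintf("%.2f%%", 100 * nt$ntcp_proton), "-"),
                       NTCP_photon = ifelse(nt$report_absolute,
                                            sprintf("%.2f%%", 100 * nt$ntcp_photon), "-"),
                       RNTCP = signif(nt$rntcp, 2), flag = nt$flag)
    print(hum2, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten a comparison result to one long data frame
#'
#' Joins the NTCP table with the per-structure relative-risk columns (or
#' returns the RR table alone when no NTCP rows exist), suitable for CSV
#' export at full precision.
#'
#' @param x A `cardrisk_result`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data frame.
#' @export
as.data.frame.cardrisk_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  if (!nrow(x$ntcp)) return(cbind(patient = x$patient, x$rr))
  merged <- merge(x$ntcp, x$rr, by = "structure", sort = FALSE)
  cbind(patient = x$patient, merged)
}
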