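# Synthetic DVH generator: stands in for treatment-planning-system exports
# so the whole pipeline is testable from code alone. Shapes are invented;
# the mean doses they are pinned to are the published per-structure means
# of the two reference cases.

#' Settings for the synthetic DVH generator
#'
#' @param seed Integer seed; identical seed and template give bit-identical
#'   output.
#' @param bin_width Dose grid width, Gy (default 0.05).
#' @param mean_tolerance Maximum allowed relative deviation of the
#'   generated mean dose from its target (default 0.5%); generation fails
#'   rather than exceed it. In practice the final affine dose-axis rescale
#'   pins the mean to the target exactly.
#' @param volume_jitter Standard deviation of the lognormal per-bin volume
#'   jitter that roughens the logistic shape (0 disables jitter).
#' @return An object of class `generator_settings`.
#' @export
generator_settings <- function(seed = 1L, bin_width = 0.05,
                               mean_tolerance = 0.005, volume_jitter = 0.05) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (mean_tolerance <= 0) stop("`mean_tolerance` must be positive")
  if (volume_jitter < 0) stop("`volume_jitter` must be non-negative")
  out <- list(seed = as.integer(seed), bin_width = bin_width,
              mean_tolerance = mean_tolerance, volume_jitter = volume_jitter)
  class(out) <- "generator_settings"
  out
}

#' Generate a synthetic differential DVH with a prescribed mean dose
#'
#' Three shape families:
#' \describe{
#'   \item{`uniform`}{all volume at the target dose (a single bin).}
#'   \item{`two_level`}{a fraction `heterogeneity` of the volume at
#'     `target_mean / heterogeneity`, the rest at zero dose — the textbook
#'     partial-volume configuration.}
#'   \item{`logistic`}{volume distributed so the cumulative DVH is a
#'     logistic fall-off centred at the target with scale `heterogeneity`
#'     (Gy), truncated at zero dose, with seeded lognormal volume jitter —
#'     emulating the smooth in-field/penumbra mix of planning-system
#'     exports.}
#' }
#' A final affine rescale of the dose axis pins the mean dose to
#' `target_mean` exactly, keeping generation deterministic.
#'
#' @param target_mean Target mean dose (>= 0); 0 puts all volume in a
#'   zero-dose bin.
#' @param shape Shape family.
#' @param heterogeneity Spread parameter: irradiated volume fraction in
#'   (0, 1] for `two_level`, logistic scale in dose units for `logistic`;
#'   ignored for `uniform`.
#' @param settings A [generator_settings()].
#' @param structure,unit Metadata for the emitted DVH.
#' @return A valid `dvh_differential` whose mean equals `target_mean`.
#' @export
generate_dvh <- function(target_mean,
                         shape = c("logistic", "uniform", "two_level"),
                         heterogeneity = 1,
                         settings = generator_settings(),
                         structure = "structure", unit = "Gy") {
  shape <- match.arg(shape)
  stopifnot(inherits(settings, "generator_settings"))
  if (target_mean < 0) stop("`target_mean` must be non-negative")
  w <- settings$bin_width
  if (target_mean == 0)
    return(dvh_differential(0, 1, structure, unit, bin_width = w))
  dvh <- switch(shape,
    uniform = dvh_differential(target_mean, 1, structure, unit, bin_width = w),
    two_level = {
      f <- heterogeneity
      if (f <= 0 || f > 1)
        stop("two_level heterogeneity must be an irradiated volume fraction in (0, 1]")
      if (f == 1)
        dvh_differential(target_mean, 1, structure, unit, bin_width = w)
      else
        dvh_differential(c(0, target_mean / f), c(1 - f, f), structure, unit,
                         bin_width = target_mean / f)
    },
    logistic = {
      h <- heterogeneity
      if (h <= 0) stop("logistic heterogeneity (spread, Gy) must be positive")
      upper <- target_mean + 10 * h
      edges <- seq(0, upper + w, by = w)
      cum <- stats::plogis((target_mean - edges) / h)
      v <- cum[-length(cum)] - cum[-1]
      centers <- edges[-length(edges)] + w / 2
      if (settings$volume_jitter > 0) {
        jit <- withr::with_seed(settings$seed,
          stats::rnorm(length(v), 0, settings$volume_jitter))
        v <- v * exp(jit)
      }
      raw <- dvh_differential(centers, v, structure, unit, bin_width = w,
                              normalize = TRUE)
      scale <- target_mean / mean_dose(raw)
      dvh_differential(raw$dose * scale, raw$volume, structure, unit,
                       bin_width = w * scale)
    })
  err <- abs(mean_dose(dvh) - target_mean) / target_mean
  if (err > settings$mean_tolerance)
    stop(sprintf("generated mean misses target by %.3g (tolerance %.3g)",
                 err, settings$mean_tolerance))
  dvh
}

# Fixed per-template DVH spreads (Gy) for the logistic shape family: broad
# in-field heterogeneity for the mediastinal plans and the craniospinal
# photon exit dose, and a narrow near-zero distribution for the
# craniospinal proton primary dose (out-of-field scatter only).
.template_spreads <- list(
  HD = list(proton = 3.0, photon = 3.0),
  MB = list(proton = 0.06, photon = 2.5)
)

#' Build a fully synthetic comparison case
#'
#' Emits a run-ready [cardrisk_case()] for one of the two shipped
#' templates, `"HD"` (mediastinal irradiation, broad in-field heart dose
#' from both modalities) or `"MB"` (craniospinal irradiation: moderate
#' photon exit dose, near-zero proton primary dose plus neutron bath). Per
#' structure and modality a logistic-shaped DVH is generated whose mean is
#' pinned to the published mean-dose table ([cardiac_dose_table()]): proton
#' DVHs in Sv at the RBE-weighted primary mean (`1.1 * primary_gy`; the
#' stray neutron bath is added later by the pipeline), photon DVHs in Gy at
#' the photon mean. With `dir` set, the DVH files and a YAML case
#' configuration are also written to disk.
#'
#' @param template `"HD"` or `"MB"`.
#' @param settings A [generator_settings()]; sub-seeds are derived per
#'   structure and modality from `settings$seed`.
#' @param dir Optional output directory for DVH files plus `case.yaml`.
#' @return A `cardrisk_case` (invisibly carrying the config path in
#'   attribute `"config"` when `dir` was given).
#' @export
build_case <- function(template = c("HD", "MB"),
                       settings = generator_settings(), dir = NULL) {
  template <- match.arg(template)
  tab <- cardiac_dose_table()
  tab <- tab[tab$patient == template, , drop = FALSE]
  spreads <- .template_spreads[[template]]
  wf <- weighting_factors(
    wr_neutron = tab$wr_neutron[tab$structure == "whole_heart"])
  dvhs <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    sp <- settings
    sp$seed <- settings$seed + 10L * i
    proton <- generate_dvh(row$primary_gy * wf$wr_proton_primary, "logistic",
                           spreads$proton, sp, row$structure, "Sv")
    sp$seed <- settings$seed + 10L * i + 1L
    photon <- generate_dvh(row$photon_gy, "logistic", spreads$photon, sp,
                           row$structure, "Gy")
    dvhs[[row$structure]] <- list(proton = proton, photon = photon)
  }
  case <- cardrisk_case(template, tab, dvhs,
                        reference_fractionation(template), wf)
  if (!is.null(dir)) {
    cfg <- write_case_config(case, dir)
    attr(case, "config") <- cfg
  }
  case
}

# Volume-weighted mixture of two differential DVHs on a common grid.
.mix_dvh <- function(a, b, w_a, structure = a$structure) {
  stopifnot(inherits(a, "dvh_differential"), inherits(b, "dvh_differential"))
  if (!identical(a$unit, b$unit)) stop("cannot mix DVHs with different units")
  if (w_a < 0 || w_a > 1) stop("mixing weight must lie in [0, 1]")
  w <- min(a$bin_width, b$bin_width, na.rm = TRUE)
  if (!is.finite(w)) stop("mixing requires at least one uniform-grid DVH")
  ra <- rebin_dvh(a, w)
  rb <- rebin_dvh(b, w)
  n <- max(length(ra$volume), length(rb$volume))
  pad <- function(x) c(x$volume, rep(0, n - length(x$volume)))
  v <- w_a * pad(ra) + (1 - w_a) * pad(rb)
  centers <- (seq_len(n) - 0.5) * w
  last <- max(which(v > 0))
  dvh_differential(centers[seq_len(last)], v[seq_len(last)], structure,
                   a$unit, bin_width = w, normalize = TRUE)
}

#' Derive a contour-variant case with thicker shell structures
#'
#' Emulates re-contouring the pericardium as a shell `thickness_factor`
#' times thicker (and the myocardium correspondingly displaced inward)
#' without any imaging: the revised pericardium DVH is a volume-weighted
#' mixture of the baseline pericardium DVH (weight `1/thickness_factor`)
#' and the myocardium DVH, and the revised myocardium is an equal mixture
#' of the myocardium and whole-heart DVHs. Purely deterministic; mixing
#' weights sum to one, so fractional volume is conserved. The mean-dose
#' table is left untouched (the mean-dose relative-risk path uses the whole
#' heart, which is unaffected by shell re-contouring).
#'
#' @param case A [cardrisk_case()] with DVHs for pericardium, myocardium
#'   and whole heart.
#' @param thickness_factor Shell thickness multiplier (>= 1); 1 returns
#'   the case unchanged.
#' @return A new `cardrisk_case` with revised DVHs.
#' @export
perturb_contour_variant <- function(case, thickness_factor = 5) {
  stopifnot(inherits(case, "cardrisk_case"))
  if (thickness_factor < 1) stop("`thickness_factor` must be >= 1")
  if (thickness_factor == 1) return(case)
  need <- c("pericardium", "myocardium", "whole_heart")
  if (!all(need %in% names(case$dvhs)))
    stop("contour perturbation needs DVHs for: ", paste(need, collapse = ", "))
  dvhs <- case$dvhs
  for (mod in c("proton", "photon")) {
    peri <- case$dvhs$pericardium[[mod]]
    myo <- case$dvhs$myocardium[[mod]]
    heart <- case$dvhs$whole_heart[[mod]]
    if (is.null(peri) || is.null(myo) || is.null(heart)) next
    dvhs$pericardium[[mod]] <- .mix_dvh(peri, myo, 1 / thickness_factor,
                                        "pericardium")
    dvhs$myocardium[[mod]] <- .mix_dvh(myo, heart, 0.5, "myocardium")
  }
  cardrisk_case(case$patient, case$dose_table, dvhs, case$fractionation,
                case$weighting)
}
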