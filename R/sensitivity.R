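# Sensitivity analyses: NTCP-parameter grid sweeps, neutron
# weighting-factor scaling, and contour-variant comparisons.

#' Sweep NTCP model parameters over a grid
#'
#' Evaluates the proton/photon NTCP ratio for one structure over the full
#' Cartesian grid of the supplied parameter axes. The structure's DVHs are
#' processed once ([prepare_equivalent_dvh()]) and reused at every grid
#' point, so the sweep is a pure function of the parameters. Grid points
#' outside the model's validity (non-positive `d50`/`gamma`/`m`/`n_vol`,
#' `s` or `n_vol` outside (0, 1]) are skipped with a warning.
#'
#' @param case A [cardrisk_case()] providing proton and photon DVHs for
#'   `structure`.
#' @param structure Structure name.
#' @param model `"rs"` (axes among `d50`, `gamma`, `s`) or `"lyman"` (axes
#'   among `d50`, `n_vol`, `m`; `d50` is `TD50(1)`).
#' @param axes Named list of numeric grids, e.g.
#'   `list(d50 = c(40, 60, 80), m = c(0.1, 0.5))`. Axes omitted here must
#'   be supplied as scalars in `fixed`.
#' @param fixed Named list of scalar parameter values for axes not swept.
#' @param neutron_scale Optional stray-dose multiplier override.
#' @param eps Zero threshold for [compute_rntcp()].
#' @return An object of class `cardrisk_sweep`: a list with `grid` (long
#'   data frame: one row per grid point with the parameter values,
#'   `ntcp_proton`, `ntcp_photon`, `rntcp`, `flag`) and `summary` (named
#'   vector with the grid minimum and maximum RNTCP).
#' @export
sweep_parameters <- function(case, structure, model = c("rs", "lyman"),
                             axes, fixed = list(), neutron_scale = NULL,
                             eps = 1e-12) {
  stopifnot(inherits(case, "cardrisk_case"))
  model <- match.arg(model)
  wanted <- if (model == "rs") c("d50", "gamma", "s") else c("d50", "n_vol", "m")
  all_axes <- c(axes, fixed)
  miss <- setdiff(wanted, names(all_axes))
  if (length(miss))
    stop("missing parameter axes: ", paste(miss, collapse = ", "))
  if (any(!lengths(axes)))
    stop("every sweep axis must be non-empty")
  grid <- do.call(expand.grid,
                  c(all_axes[wanted], KEEP.OUT.ATTRS = FALSE))
  dvh_p <- prepare_equivalent_dvh(case, structure, "proton", neutron_scale)
  dvh_q <- prepare_equivalent_dvh(case, structure, "photon", neutron_scale)
  np <- nq <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    valid <- if (model == "rs")
      g$d50 > 0 && g$gamma > 0 && g$s > 0 && g$s <= 1
    else
      g$d50 > 0 && g$m > 0 && g$n_vol > 0 && g$n_vol <= 1
    if (!valid) {
      warning(sprintf("skipping invalid grid point %d", i))
      next
    }
    if (model == "rs") {
      pars <- rs_params(g$d50, g$gamma, g$s)
      np[i] <- ntcp_relative_seriality(dvh_p, pars)
      nq[i] <- ntcp_relative_seriality(dvh_q, pars)
    } else {
      pars <- lyman_params(g$d50, g$n_vol, g$m)
      np[i] <- ntcp_lyman_dvh(dvh_p, pars)
      nq[i] <- ntcp_lyman_dvh(dvh_q, pars)
    }
  }
  ok <- !is.na(np)
  rat <- data.frame(rntcp = rep(NA_real_, nrow(grid)),
                    flag = rep(NA_character_, nrow(grid)))
  if (any(ok)) rat[ok, ] <- compute_rntcp(np[ok], nq[ok], eps)
  grid$ntcp_proton <- np
  grid$ntcp_photon <- nq
  grid$rntcp <- rat$rntcp
  grid$flag <- rat$flag
  finite <- is.finite(grid$rntcp)
  out <- list(structure = structure, model = model, grid = grid,
              summary = c(min = if (any(finite)) min(grid$rntcp[finite]) else NA_real_,
                          max = if (any(finite)) max(grid$rntcp[finite]) else NA_real_))
  class(out) <- "cardrisk_sweep"
  out
}

#' @export
print.cardrisk_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %s (%s model), %d grid points, RNTCP in [%.3g, %.3g]\n",
              x$structure, x$model, nrow(x$grid),
              x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' Named extreme parameter combinations for ratio bounds
#'
#' The published minimum/maximum parameter combinations used to bracket the
#' NTCP ratio per structure: pericardium (Lyman) min
#' `TD50 = 40, n = 1, m = 0.05` / max `TD50 = 80, n = 0.2, m = 0.5`;
#' myocardium and whole heart (relative seriality) min
#' `D50 = 40, gamma = 1.5, s = 0.5` / max `D50 = 80, gamma = 0.8, s = 1`.
#'
#' @return A data frame of named presets in the layout of
#'   [cardiac_param_sets()] plus a `bound` column.
#' @export
rntcp_extreme_presets <- function() {
  data.frame(
    structure = c("pericardium", "pericardium", "myocardium", "myocardium",
                  "whole_heart", "whole_heart"),
    bound = rep(c("min", "max"), 3),
    set_id = c("pericardium_min", "pericardium_max", "myocardium_min",
               "myocardium_max", "whole_heart_min", "whole_heart_max"),
    source = "extreme_preset",
    model = c("lyman", "lyman", "rs", "rs", "rs", "rs"),
    d50 = c(40, 80, 40, 80, 40, 80),
    n_vol = c(1, 0.2, NA, NA, NA, NA),
    m = c(0.05, 0.5, NA, NA, NA, NA),
    gamma = c(NA, NA, 1.5, 0.8, 1.5, 0.8),
    s = c(NA, NA, 0.5, 1, 0.5, 1),
    hd_applicable = FALSE,
    stringsAsFactors = FALSE
  )
}

#' RRR (and optionally RNTCP) as a function of neutron weighting scale
#'
#' Re-runs the mean-dose relative-risk comparison, and where DVHs and
#' parameter sets are available the NTCP comparison, with the stray neutron
#' equivalent dose multiplied by each factor in `factors`. Only the proton
#' plan carries a separate neutron term, so RRR is continuous and strictly
#' increasing in the scaling factor.
#'
#' @param case A [cardrisk_case()].
#' @param factors Numeric vector of non-negative scaling factors.
#' @param param_sets Optional parameter-set table; when supplied and the
#'   case has DVHs, RNTCP values are computed per factor as well.
#' @param eps Zero threshold for [compute_rntcp()].
#' @return A list with `rrr` (long data frame: factor, structure, RRs, RRR)
#'   and `rntcp` (long data frame or NULL).
#' @export
sweep_neutron_wr <- function(case, factors, param_sets = NULL, eps = 1e-12) {
  stopifnot(inherits(case, "cardrisk_case"))
  if (any(factors < 0)) stop("scaling factors must be non-negative")
  rrr_rows <- list()
  rn_rows <- list()
  for (f in factors) {
    res <- run_case(case,
                    param_sets = if (is.null(param_sets))
                      cardiac_param_sets()[0, ] else param_sets,
                    neutron_scale = f, eps = eps)
    rrr_rows[[length(rrr_rows) + 1L]] <-
      cbind(factor = f, res$rr[, c("structure", "rr_proton", "rr_photon", "rrr")])
    if (!is.null(param_sets) && nrow(res$ntcp))
      rn_rows[[length(rn_rows) + 1L]] <-
        cbind(factor = f,
              res$ntcp[, c("structure", "set_id", "ntcp_proton",
                           "ntcp_photon", "rntcp", "flag")])
  }
  list(rrr = do.call(rbind, rrr_rows),
       rntcp = if (length(rn_rows)) do.call(rbind, rn_rows) else NULL)
}

#' Neutron scaling factor at which RRR crosses unity
#'
#' Solves `RRR(f) = 1` for the stray-dose scaling factor `f` by root
#' finding. Since both relative risks are affine in dose, the crossing
#' satisfies the closed form
#' `f* = (wr_photon * D_photon - wr_primary * D_primary) / H_stray`.
#'
#' @param case A [cardrisk_case()].
#' @param structure Structure whose mean doses define the RRs (default
#'   `"whole_heart"`).
#' @param interval Search interval for the factor.
#' @return The crossing factor (may lie outside `interval`'s physical
#'   sweep range; an error is raised if no sign change exists within it).
#' @export
rrr_unity_crossing <- function(case, structure = "whole_heart",
                               interval = c(1e-6, 100)) {
  stopifnot(inherits(case, "cardrisk_case"))
  row <- case$dose_table[case$dose_table$structure == structure, ]
  if (!nrow(row)) stop("structure '", structure, "' not in dose table")
  wf <- case$weighting
  f_of <- function(f) {
    dp <- total_mean_equivalent_dose(row$primary_gy, wf$wr_proton_primary,
                                     row$stray_sv, f)
    dq <- equivalent_dose(row$photon_gy, wf$wr_photon)
    compute_rrr(relative_risk(dp)$rr, relative_risk(dq)$rr) - 1
  }
  stats::uniroot(f_of, interval, tol = 1e-12)$root
}

#' Compare NTCP ratios between two contour variants of the same plans
#'
#' Runs the pipeline on two cases that share modality structure (typically
#' a baseline and a revised-contour variant, see
#' [perturb_contour_variant()]) and tabulates their RNTCP values side by
#' side.
#'
#' @param case_a,case_b Two [cardrisk_case()] objects.
#' @param param_sets Parameter-set table, see [cardiac_param_sets()].
#' @param eps Zero threshold for [compute_rntcp()].
#' @return A data frame with one row per structure/parameter set and
#'   columns `rntcp_a` and `rntcp_b`.
#' @export
compare_contour_variants <- function(case_a, case_b,
                                     param_sets = cardiac_param_sets(),
                                     eps = 1e-12) {
  res_a <- run_case(case_a, param_sets, eps = eps)$ntcp
  res_b <- run_case(case_b, param_sets, eps = eps)$ntcp
  merged <- merge(res_a[, c("structure", "set_id", "model", "rntcp")],
                  res_b[, c("structure", "set_id", "rntcp")],
                  by = c("structure", "set_id"), sort = FALSE,
                  suffixes = c("_a", "_b"))
  merged
}
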