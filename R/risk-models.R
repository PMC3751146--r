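# Dose-response models: linear relative risk of cardiac mortality,
# relative-seriality (Kallman/Poisson) NTCP, and Lyman NTCP with
# effective-volume reduction for inhomogeneous dose.

#' Linear relative-risk model parameters
#'
#' Cardiac-mortality dose response fitted on childhood cancer survivor
#' cohorts: `RR = 1 + alpha1 * D` with `D` the mean heart dose. The default
#' slope is 0.6 per Gy with 95% CI 0.2 to 2.5.
#'
#' @param alpha1 Excess relative risk per Gy (> 0).
#' @param ci Length-2 numeric, 95% confidence bounds on `alpha1`
#'   (`ci[1] <= alpha1 <= ci[2]`).
#' @return An object of class `linear_risk_params`.
#' @export
linear_risk_params <- function(alpha1 = 0.6, ci = c(0.2, 2.5)) {
  if (alpha1 <= 0) stop("`alpha1` must be positive")
  if (length(ci) != 2L || ci[1] > alpha1 || ci[2] < alpha1)
    stop("`ci` must be bounds enclosing `alpha1`")
  out <- list(alpha1 = alpha1, ci = as.numeric(ci))
  class(out) <- "linear_risk_params"
  out
}

#' Relative-seriality model parameters
#'
#' @param d50 Uniform whole-organ dose giving a 50% complication
#'   probability, Gy (> 0).
#' @param gamma Maximum normalized slope of the dose-response curve (> 0).
#' @param s Relative seriality in (0, 1]: 1 is a fully serial organ,
#'   values near 0 approach parallel architecture.
#' @return An object of class `rs_params`.
#' @export
rs_params <- function(d50, gamma, s) {
  if (d50 <= 0) stop("`d50` must be positive")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (s <= 0 || s > 1) stop("`s` must lie in (0, 1]")
  out <- list(d50 = d50, gamma = gamma, s = s)
  class(out) <- "rs_params"
  out
}

#' Lyman model parameters
#'
#' @param td50_full Tolerance dose giving 50% complication probability for
#'   uniform irradiation of the full organ, `TD50(1)`, Gy (> 0).
#' @param n_vol Volume-effect exponent in (0, 1]; values near 1 mean a
#'   strong volume effect. (Distinct from the voxel count of the
#'   relative-seriality product.)
#' @param m Slope parameter, inversely proportional to the steepness of the
#'   dose-response curve (> 0).
#' @return An object of class `lyman_params`.
#' @export
lyman_params <- function(td50_full, n_vol, m) {
  if (td50_full <= 0) stop("`td50_full` must be positive")
  if (n_vol <= 0 || n_vol > 1) stop("`n_vol` must lie in (0, 1]")
  if (m <= 0) stop("`m` must be positive")
  out <- list(td50_full = td50_full, n_vol = n_vol, m = m)
  class(out) <- "lyman_params"
  out
}

#' Relative risk of cardiac toxicity from mean heart dose
#'
#' `RR = 1 + alpha1 * D`, with confidence bounds obtained by substituting
#' the confidence limits of the slope.
#'
#' @param dose Mean heart dose (Gy or Sv; the linear slope was fitted on
#'   mean dose and is applied to the total mean equivalent dose for proton
#'   plans). Vectorized, >= 0.
#' @param params A [linear_risk_params()] object.
#' @return A data frame with columns `dose`, `rr`, `rr_lower`, `rr_upper`.
#' @examples
#' relative_risk(10.45)  # RR 7.27, CI 3.09 to 27.12
#' @export
relative_risk <- function(dose, params = linear_risk_params()) {
  stopifnot(inherits(params, "linear_risk_params"))
  if (any(dose < 0)) stop("mean dose must be non-negative")
  data.frame(dose = dose,
             rr = 1 + params$alpha1 * dose,
             rr_lower = 1 + params$ci[1] * dose,
             rr_upper = 1 + params$ci[2] * dose)
}

#' Poisson dose-response of the relative-seriality model
#'
#' Probability of complication for a subvolume uniformly irradiated to dose
#' `D`: `P(D) = 2^(-exp(e * gamma * (1 - D/D50)))`, the Kallman form, in
#' which `D50` gives exactly 0.5 and `gamma` is the maximum normalized
#' slope.
#'
#' @param dose Dose (vectorized, >= 0).
#' @param params An [rs_params()] object (`s` is not used here).
#' @return Probabilities in (0, 1), strictly increasing in dose.
#' @export
poisson_response <- function(dose, params) {
  stopifnot(inherits(params, "rs_params"))
  if (any(dose < 0)) stop("`dose` must be non-negative")
  exp(log(2) * -exp(exp(1) * params$gamma * (1 - dose / params$d50)))
}

# log P(D) for the Poisson response, used by the log-space DVH reduction.
.log_poisson_response <- function(dose, params) {
  log(2) * -exp(exp(1) * params$gamma * (1 - dose / params$d50))
}

#' Relative-seriality NTCP for an inhomogeneous dose distribution
#'
#' Evaluates
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^(v_i))^(1/s)`
#' over the bins of a differential DVH, where `v_i` is the fractional
#' volume of bin `i`. Computed in log space so that very small per-bin
#' response probabilities do not underflow; results below `1e-300` are
#' reported as 0. For a uniform whole-organ dose the expression collapses
#' to `P(D)` for every `s`.
#'
#' @param dvh A `dvh_differential` (equivalent/EQD2-corrected dose axis in
#'   the intended use; the model itself is unit-agnostic).
#' @param params An [rs_params()] object.
#' @return NTCP in \[0, 1\].
#' @export
ntcp_relative_seriality <- function(dvh, params) {
  stopifnot(inherits(dvh, "dvh_differential"), inherits(params, "rs_params"))
  validate_dvh(dvh)
  logp <- .log_poisson_response(dvh$dose, params)
  log_ps <- params$s * logp                    # log P^s, <= 0
  terms <- dvh$volume * log1p(-exp(log_ps))    # v_i * log(1 - P^s)
  total <- sum(terms)
  inner <- -expm1(total)                       # 1 - prod(...)
  if (inner <= 0) return(0)
  out <- exp(log(inner) / params$s)
  if (out < 1e-300) 0 else min(out, 1)
}

#' Partial-volume tolerance dose of the Lyman model
#'
#' `TD50(V) = TD50(1) / V^n`: the uniform dose to a partial volume `V`
#' giving 50% complication probability.
#'
#' @param td50_full `TD50(1)`, Gy.
#' @param V Irradiated volume fraction in (0, 1]. Vectorized.
#' @param n_vol Volume-effect exponent.
#' @return `TD50(V)` in Gy.
#' @export
td50_partial <- function(td50_full, V, n_vol) {
  if (any(V <= 0) || any(V > 1)) stop("`V` must lie in (0, 1]")
  if (td50_full <= 0) stop("`td50_full` must be positive")
  td50_full / V^n_vol
}

#' Lyman NTCP for uniform partial-volume irradiation
#'
#' `NTCP = Phi(t)` with `t = (D - TD50(V)) / (m * TD50(V))`, the standard
#' normal CDF of the standardized dose. Values below `1e-300` are reported
#' as 0.
#'
#' @param dose Uniform dose to the irradiated volume (>= 0). Vectorized.
#' @param V Irradiated volume fraction in (0, 1].
#' @param params A [lyman_params()] object.
#' @return NTCP in \[0, 1\].
#' @export
ntcp_lyman_uniform <- function(dose, V, params) {
  stopifnot(inherits(params, "lyman_params"))
  if (any(dose < 0)) stop("`dose` must be non-negative")
  td50v <- td50_partial(params$td50_full, V, params$n_vol)
  t <- (dose - td50v) / (params$m * td50v)
  p <- stats::pnorm(t)
  ifelse(p < 1e-300, 0, p)
}

#' Lyman NTCP for an inhomogeneous dose distribution
#'
#' Reduces the differential DVH to an equivalent uniform partial-volume
#' irradiation and delegates to [ntcp_lyman_uniform()]. The default is the
#' Kutcher-Burman effective-volume reduction evaluated at the maximum DVH
#' dose, `V_eff = sum_i v_i * (D_i / D_max)^(1/n)`, the standard companion
#' to the Lyman model; `reduction = "geud"` instead evaluates the
#' generalized equivalent uniform dose `(sum_i v_i * D_i^(1/n))^n` at full
#' volume. For a two-level DVH with a single irradiated level both reduce
#' exactly to the partial-volume formula.
#'
#' @param dvh A `dvh_differential`.
#' @param params A [lyman_params()] object.
#' @param reduction `"effective_volume"` (Kutcher-Burman, default) or
#'   `"geud"`.
#' @return NTCP in \[0, 1\].
#' @export
ntcp_lyman_dvh <- function(dvh, params,
                           reduction = c("effective_volume", "geud")) {
  stopifnot(inherits(dvh, "dvh_differential"), inherits(params, "lyman_params"))
  reduction <- match.arg(reduction)
  validate_dvh(dvh)
  pos <- dvh$volume > 0
  d <- dvh$dose[pos]
  v <- dvh$volume[pos]
  dmax <- max(d)
  if (dmax <= 0) return(ntcp_lyman_uniform(0, 1, params))
  if (reduction == "effective_volume") {
    veff <- sum(v * (d / dmax)^(1 / params$n_vol))
    ntcp_lyman_uniform(dmax, veff, params)
  } else {
    eud <- sum(v * d^(1 / params$n_vol))^params$n_vol
    ntcp_lyman_uniform(eud, 1, params)
  }
}
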