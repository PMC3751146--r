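# DVH containers and plain-text I/O.
#
# A differential DVH stores, per dose bin, the fraction of a structure's
# volume receiving that bin's dose; fractional volumes sum to one, so the
# absolute organ volume is never needed downstream. A cumulative DVH stores
# the volume fraction receiving at least each threshold dose. All risk
# models in this package consume the differential form; the cumulative form
# exists for interchange with treatment-planning-system exports.

.dose_units <- c("Gy", "Sv")
.vol_tol <- 1e-9

#' Construct a differential dose-volume histogram
#'
#' @param dose Numeric vector of bin-center doses, strictly increasing and
#'   non-negative.
#' @param volume Numeric vector of fractional volumes, one per bin. Must be
#'   non-negative and sum to one (within `1e-9`) unless `normalize = TRUE`.
#' @param structure Name of the anatomical structure.
#' @param unit Dose unit: `"Gy"` for absorbed / RBE-weighted dose, `"Sv"`
#'   for equivalent dose. The unit is carried as metadata and checked by
#'   operations that require a specific scale.
#' @param bin_width Common bin width in dose units. Inferred from the dose
#'   grid when the spacing is uniform; `NA` marks a non-uniform grid (e.g.
#'   after a non-linear dose transform), in which case operations that need
#'   bin edges refuse to run.
#' @param normalize If `TRUE`, rescale `volume` to sum to one. Use when
#'   reading absolute-volume (cm^3) exports.
#' @return An object of class `dvh_differential`.
#' @examples
#' dvh <- dvh_differential(c(5, 15), c(0.5, 0.5), "whole_heart", "Gy")
#' mean_dose(dvh)
#' @export
dvh_differential <- function(dose, volume, structure = "structure",
                             unit = c("Gy", "Sv"), bin_width = NULL,
                             normalize = FALSE) {
  unit <- match.arg(unit)
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) != length(volume) || length(dose) == 0L)
    stop("`dose` and `volume` must be non-empty vectors of equal length")
  if (normalize) {
    tot <- sum(volume)
    if (!is.finite(tot) || tot <= 0)
      stop("cannot normalize: total volume is not positive")
    volume <- volume / tot
  }
  if (is.null(bin_width)) bin_width <- .infer_bin_width(dose)
  out <- list(structure = as.character(structure)[1], unit = unit,
              dose = dose, volume = volume, bin_width = as.numeric(bin_width))
  class(out) <- c("dvh_differential", "dvh")
  validate_dvh(out)
  out
}

#' Construct a cumulative dose-volume histogram
#'
#' Points give the volume fraction receiving at least each threshold dose.
#'
#' @param dose Numeric vector of dose thresholds, strictly increasing.
#' @param volume Volume fractions at each threshold: non-increasing, first
#'   value 1, last value >= 0.
#' @inheritParams dvh_differential
#' @return An object of class `dvh_cumulative`.
#' @export
dvh_cumulative <- function(dose, volume, structure = "structure",
                           unit = c("Gy", "Sv")) {
  unit <- match.arg(unit)
  out <- list(structure = as.character(structure)[1], unit = unit,
              dose = as.numeric(dose), volume = as.numeric(volume))
  class(out) <- c("dvh_cumulative", "dvh")
  validate_dvh(out)
  out
}

.infer_bin_width <- function(dose) {
  if (length(dose) < 2L) return(NA_real_)
  steps <- diff(dose)
  if (max(steps) - min(steps) <= 1e-9 * max(abs(steps), 1)) steps[1]
  else NA_real_
}

#' Validate a DVH object
#'
#' Checks the structural invariants of a DVH and stops with an informative
#' error when one is violated. Called by all constructors; exported so that
#' pipelines can re-check objects after manual edits.
#'
#' @param x A `dvh_differential` or `dvh_cumulative` object.
#' @return `x`, invisibly, if valid.
#' @export
validate_dvh <- function(x) {
  if (!inherits(x, "dvh")) stop("not a DVH object")
  if (!x$unit %in% .dose_units)
    stop("unknown dose unit: ", x$unit)
  if (anyNA(x$dose) || anyNA(x$volume))
    stop("DVH contains missing values")
  if (any(x$dose < 0)) stop("DVH doses must be non-negative")
  if (length(x$dose) > 1L && any(diff(x$dose) <= 0))
    stop("DVH dose axis must be strictly increasing")
  if (inherits(x, "dvh_differential")) {
    if (any(x$volume < -.vol_tol))
      stop("differential DVH volumes must be non-negative")
    if (abs(sum(x$volume) - 1) > .vol_tol)
      stop(sprintf("differential DVH volumes must sum to 1 (got %.12g)",
                   sum(x$volume)))
    if (!is.na(x$bin_width) && length(x$dose) > 1L) {
      steps <- diff(x$dose)
      if (any(abs(steps - x$bin_width) > 1e-6 * max(x$bin_width, 1e-12)))
        stop("bin centers are not uniformly spaced at the declared bin width")
    }
  } else {
    if (any(diff(x$volume) > .vol_tol))
      stop("cumulative DVH volume must be non-increasing in dose")
    if (abs(x$volume[1] - 1) > .vol_tol)
      stop("cumulative DVH must start at volume fraction 1")
    if (x$volume[length(x$volume)] < -.vol_tol)
      stop("cumulative DVH volumes must be non-negative")
  }
  invisible(x)
}

#' @export
print.dvh_differential <- function(x, ...) {
  cat(sprintf("Differential DVH: %s [%s], %d bins, mean dose %.4g %s\n",
              x$structure, x$unit, length(x$dose), mean_dose(x), x$unit))
  invisible(x)
}

#' @export
print.dvh_cumulative <- function(x, ...) {
  cat(sprintf("Cumulative DVH: %s [%s], %d points, D_max %.4g %s\n",
              x$structure, x$unit, length(x$dose), max(x$dose), x$unit))
  invisible(x)
}

#' Mean dose of a DVH
#'
#' For a differential DVH this is the volume-weighted mean of the bin-center
#' doses, `sum(v_i * D_i)`. Cumulative DVHs are converted first, so the mean
#' is invariant under differential/cumulative round trips.
#'
#' @param x A DVH object.
#' @return Mean dose in the DVH's unit.
#' @export
mean_dose <- function(x) UseMethod("mean_dose")

#' @export
mean_dose.dvh_differential <- function(x) sum(x$volume * x$dose)

#' @export
mean_dose.dvh_cumulative <- function(x) mean_dose(dvh_to_differential(x))

#' Convert a differential DVH to cumulative form
#'
#' The cumulative volume at threshold `d` is the sum of fractional volumes
#' over bins whose center dose is at least `d`. Thresholds are emitted at 0
#' (when the first bin center is positive), at every bin center, and one bin
#' width above the last center where the volume reaches 0, so that
#' [dvh_to_differential()] recovers the original bins exactly.
#'
#' @param dvh A `dvh_differential` object.
#' @return A `dvh_cumulative` object.
#' @export
dvh_to_cumulative <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_differential"))
  validate_dvh(dvh)
  w <- dvh$bin_width
  if (is.na(w)) {
    if (length(dvh$dose) < 2L)
      stop("cumulative conversion of a single-bin DVH needs a bin width")
    w <- mean(diff(dvh$dose))
  }
  th <- dvh$dose
  if (th[1] > 0) th <- c(0, th)
  th <- c(th, max(dvh$dose) + w)
  vol <- vapply(th, function(t) sum(dvh$volume[dvh$dose >= t - 1e-12]),
                numeric(1))
  dvh_cumulative(th, vol, dvh$structure, dvh$unit)
}

#' Convert a cumulative DVH to differential form
#'
#' Mass between consecutive thresholds is assigned to the lower threshold
#' dose; any residual volume at the last threshold is kept as a final bin.
#' Bins with zero volume are dropped.
#'
#' @param cdvh A `dvh_cumulative` object.
#' @return A `dvh_differential` object.
#' @export
dvh_to_differential <- function(cdvh) {
  stopifnot(inherits(cdvh, "dvh_cumulative"))
  validate_dvh(cdvh)
  k <- length(cdvh$dose)
  v <- c(cdvh$volume[-k] - cdvh$volume[-1], cdvh$volume[k])
  d <- cdvh$dose
  keep <- v > 1e-15
  if (!any(keep)) stop("cumulative DVH carries no volume")
  dvh_differential(d[keep], v[keep], cdvh$structure, cdvh$unit,
                   normalize = TRUE)
}

#' Rebin a differential DVH onto a new uniform grid
#'
#' Conservative redistribution: each source bin is treated as a box of
#' uniform density over its width and its volume is split across target bins
#' in proportion to geometric overlap, so total volume is preserved exactly
#' and the mean dose moves by less than one source bin width.
#'
#' @param dvh A `dvh_differential` with a known (uniform) `bin_width`.
#' @param bin_width Target bin width, > 0.
#' @return A `dvh_differential` on the new grid (bins start at dose 0).
#' @export
rebin_dvh <- function(dvh, bin_width) {
  stopifnot(inherits(dvh, "dvh_differential"), bin_width > 0)
  validate_dvh(dvh)
  w0 <- dvh$bin_width
  if (is.na(w0)) stop("rebinning requires a uniform source grid")
  lo <- pmax(0, dvh$dose - w0 / 2)
  hi <- dvh$dose + w0 / 2
  edges <- seq(0, max(hi) + bin_width, by = bin_width)
  nv <- numeric(length(edges) - 1L)
  el <- edges[-length(edges)]
  eh <- edges[-1]
  for (i in seq_along(dvh$dose)) {
    ov <- pmax(0, pmin(hi[i], eh) - pmax(lo[i], el))
    nv <- nv + dvh$volume[i] * ov / (hi[i] - lo[i])
  }
  last <- max(which(nv > 0))
  dvh_differential(el[seq_len(last)] + bin_width / 2, nv[seq_len(last)],
                   dvh$structure, dvh$unit, bin_width = bin_width,
                   normalize = TRUE)
}

#' Write a DVH to a plain-text file
#'
#' Format: one header line
#' `# structure=<name><TAB>unit=<Gy|Sv><TAB>kind=<differential|cumulative>`
#' (differential DVHs also record `bin_width`), then tab-separated
#' `dose<TAB>volume` rows at full double precision, so read/write round
#' trips are lossless.
#'
#' @param dvh A DVH object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"))
  validate_dvh(dvh)
  kind <- if (inherits(dvh, "dvh_differential")) "differential" else "cumulative"
  hdr <- sprintf("# structure=%s\tunit=%s\tkind=%s", dvh$structure, dvh$unit, kind)
  if (kind == "differential")
    hdr <- paste0(hdr, sprintf("\tbin_width=%s", format(dvh$bin_width, digits = 17)))
  rows <- sprintf("%s\t%s", format(dvh$dose, digits = 17, scientific = FALSE, trim = TRUE),
                  format(dvh$volume, digits = 17, trim = TRUE))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a DVH from a plain-text file
#'
#' Parses the format written by [write_dvh()]. Malformed rows, a
#' non-monotone dose axis, or an unknown unit raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @return A `dvh_differential` or `dvh_cumulative` object, according to the
#'   header's `kind` field.
#' @export
read_dvh <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#"))
    stop("not a DVH file (missing '# ...' header line): ", path)
  fields <- strsplit(sub("^#\\s*", "", lines[1]), "\t", fixed = TRUE)[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("malformed DVH header at line 1 of ", path)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  for (key in c("structure", "unit", "kind"))
    if (is.na(meta[key])) stop("DVH header missing field '", key, "': ", path)
  if (!meta[["unit"]] %in% .dose_units)
    stop("unknown dose unit '", meta[["unit"]], "' at line 1 of ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed DVH row at line %d of %s", bad[1] + 1L, path))
  dose <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  volume <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(dose) | is.na(volume))
  if (length(bad))
    stop(sprintf("non-numeric DVH row at line %d of %s", bad[1] + 1L, path))
  if (length(dose) > 1L) {
    bad <- which(diff(dose) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone dose axis at line %d of %s", bad[1] + 2L, path))
  }
  if (identical(meta[["kind"]], "differential")) {
    bw <- if (!is.na(meta["bin_width"])) as.numeric(meta[["bin_width"]]) else NULL
    dvh_differential(dose, volume, meta[["structure"]], meta[["unit"]],
                     bin_width = bw)
  } else if (identical(meta[["kind"]], "cumulative")) {
    dvh_cumulative(dose, volume, meta[["structure"]], meta[["unit"]])
  } else {
    stop("unknown DVH kind '", meta[["kind"]], "' at line 1 of ", path)
  }
}
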