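# YAML case configuration: a plain-text, schema-checked description of a
# comparison case (dose table, DVH file paths, fractionation, weighting)
# that round-trips through write_case_config()/read_case_config().

.config_structure_keys <- c("primary_gy", "stray_gy", "stray_sv", "photon_gy")

#' Write a case to a directory as DVH files plus a YAML configuration
#'
#' Emits one `<structure>_<modality>.dvh` text file per DVH and a
#' `case.yaml` holding the patient label, fraction count, alpha/beta,
#' weighting factors, per-structure mean doses and DVH file names
#' (relative to the directory).
#'
#' @param case A [cardrisk_case()].
#' @param dir Output directory (created if absent).
#' @return The path of the written `case.yaml`, invisibly.
#' @export
write_case_config <- function(case, dir) {
  stopifnot(inherits(case, "cardrisk_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structures <- list()
  for (i in seq_len(nrow(case$dose_table))) {
    row <- case$dose_table[i, ]
    st <- row$structure
    entry <- as.list(row[.config_structure_keys])
    if (!is.null(row$total_sv)) entry$total_sv <- row$total_sv
    dvh_files <- list()
    for (mod in names(case$dvhs[[st]])) {
      fn <- sprintf("%s_%s.dvh", st, mod)
      write_dvh(case$dvhs[[st]][[mod]], file.path(dir, fn))
      dvh_files[[mod]] <- fn
    }
    if (length(dvh_files)) entry$dvh <- dvh_files
    structures[[st]] <- entry
  }
  cfg <- list(
    patient = case$patient,
    fractions = case$fractionation$n_fractions,
    alpha_beta = case$fractionation$alpha_beta,
    weighting = list(wr_proton_primary = case$weighting$wr_proton_primary,
                     wr_photon = case$weighting$wr_photon,
                     wr_neutron = case$weighting$wr_neutron,
                     neutron_scale = case$weighting$neutron_scale),
    structures = structures
  )
  path <- file.path(dir, "case.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Check a case configuration file against the schema
#'
#' Verifies the presence and types of the required keys and the existence
#' of every referenced DVH file, without reading the DVHs.
#'
#' @param path Path to a `case.yaml`.
#' @return `TRUE` if valid; otherwise a character vector of problems
#'   (one per violated rule), with class `"cardrisk_config_problems"`.
#' @export
validate_case_config <- function(path) {
  problems <- character()
  if (!file.exists(path)) return(structure("config file does not exist",
                                           class = "cardrisk_config_problems"))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    structure(list(), failed = conditionMessage(e)))
  if (!is.null(attr(cfg, "failed")))
    return(structure(paste("YAML parse failure:", attr(cfg, "failed")),
                     class = "cardrisk_config_problems"))
  req <- function(key, check, what) {
    if (is.null(cfg[[key]])) problems <<- c(problems,
      sprintf("missing key '%s'", key))
    else if (!check(cfg[[key]])) problems <<- c(problems,
      sprintf("key '%s' must be %s", key, what))
  }
  req("patient", is.character, "a string")
  req("fractions", function(x) is.numeric(x) && x >= 1, "a count >= 1")
  req("alpha_beta", function(x) is.numeric(x) && x > 0, "a positive dose ratio")
  req("structures", function(x) is.list(x) && length(x) > 0,
      "a non-empty mapping")
  if (is.list(cfg$structures)) {
    base <- dirname(path)
    for (st in names(cfg$structures)) {
      entry <- cfg$structures[[st]]
      for (key in .config_structure_keys)
        if (is.null(entry[[key]]) || !is.numeric(entry[[key]]) ||
            entry[[key]] < 0)
          problems <- c(problems,
            sprintf("structures.%s.%s must be a non-negative dose", st, key))
      for (mod in names(entry$dvh))
        if (!file.exists(file.path(base, entry$dvh[[mod]])))
          problems <- c(problems,
            sprintf("structures.%s.dvh.%s references a missing file: %s",
                    st, mod, entry$dvh[[mod]]))
    }
  }
  if (length(problems))
    structure(problems, class = "cardrisk_config_problems")
  else TRUE
}

#' Read a case from a YAML configuration
#'
#' Reconstructs a [cardrisk_case()] from a `case.yaml` written by
#' [write_case_config()] (or hand-authored to the same schema). DVH paths
#' are resolved relative to the configuration file.
#'
#' @param path Path to the `case.yaml`.
#' @return A `cardrisk_case`.
#' @export
read_case_config <- function(path) {
  ok <- validate_case_config(path)
  if (!isTRUE(ok))
    stop("invalid case configuration:\n  ", paste(ok, collapse = "\n  "))
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rows <- lapply(names(cfg$structures), function(st) {
    entry <- cfg$structures[[st]]
    df <- data.frame(structure = st, stringsAsFactors = FALSE)
    for (key in .config_structure_keys) df[[key]] <- entry[[key]]
    df$total_sv <- if (is.null(entry$total_sv)) NA_real_ else entry$total_sv
    df
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$total_sv))) tab$total_sv <- NULL
  dvhs <- list()
  for (st in names(cfg$structures)) {
    entry <- cfg$structures[[st]]
    for (mod in names(entry$dvh))
      dvhs[[st]][[mod]] <- read_dvh(file.path(base, entry$dvh[[mod]]))
  }
  wcfg <- cfg$weighting
  weighting <- if (is.null(wcfg)) weighting_factors() else
    weighting_factors(
      wr_proton_primary = wcfg$wr_proton_primary %||% 1.1,
      wr_photon = wcfg$wr_photon %||% 1.0,
      wr_neutron = wcfg$wr_neutron %||% 8.5,
      neutron_scale = wcfg$neutron_scale %||% 1)
  cardrisk_case(cfg$patient, tab, dvhs,
                fractionation_scheme(cfg$fractions, cfg$alpha_beta),
                weighting)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
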