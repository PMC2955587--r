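#' Read a degradation time course from CSV
#'
#' The interchange dialect is a plain CSV with a `time_min` column followed
#' by any subset of `glcnac1_mM` .. `glcnac6_mM` (units fixed in the headers
#' to prevent silent mM/uM confusion). Empty cells mean "not measured" and
#' become `NA`.
#'
#' @param path File to read.
#'
#' @return A `time_course` tibble.
#' @export
read_time_course <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "chitokin_io_error")
  }
  raw <- tryCatch(
    # parse problems surface as a typed chitokin error below, so readr's own
    # warning is redundant
    suppressWarnings(
      readr::read_csv(path, lazy = FALSE,
                      col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE)),
    error = function(e) abort(paste0("cannot parse ", path, ": ",
                                     conditionMessage(e)),
                              class = "chitokin_parse_error")
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort(paste0(path, " is empty"), class = "chitokin_parse_error")
  }
  if (!"time_min" %in% names(raw)) {
    abort(paste0(path, ": missing required column `time_min`"),
          class = "chitokin_parse_error")
  }
  sp <- grep("^glcnac[0-9]+_mM$", names(raw), value = TRUE)
  if (length(sp) == 0) {
    abort(paste0(path, ": no `glcnacN_mM` species columns found"),
          class = "chitokin_parse_error")
  }
  extra <- setdiff(names(raw), c("time_min", sp))
  if (length(extra)) {
    abort(paste0(path, ": unrecognised column(s) ", toString(extra)),
          class = "chitokin_parse_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(path, ": non-numeric cell(s) at line(s) ",
                 toString(unique(probs$row + 1L))),
          class = "chitokin_parse_error")
  }
  if (anyNA(raw$time_min)) {
    abort(paste0(path, ": missing time value at line(s) ",
                 toString(which(is.na(raw$time_min)) + 1L)),
          class = "chitokin_parse_error")
  }
  if (is.unsorted(raw$time_min)) {
    abort(paste0(path, ": times must be sorted ascending"),
          class = "chitokin_parse_error")
  }
  out <- raw[c("time_min", sp[order(as.integer(sub("^glcnac([0-9]+)_mM$", "\\1",
                                                   sp)))])]
  class(out) <- c("time_course", class(out))
  out
}

#' @rdname read_time_course
#' @param tc A `time_course` (or compatible data frame) to write.
#' @export
write_time_course <- function(tc, path) {
  cols <- c("time_min", tc_species(tc))
  readr::write_csv(as_tibble(as.data.frame(tc))[cols], path, progress = FALSE)
  invisible(path)
}

config_sections <- c("subsites", "rates", "temperature_C", "enzyme_total_uM")

#' Model configuration files
#'
#' A model configuration is a YAML (or JSON) document with four sections:
#' `subsites` (position -> kcal/mol), `rates` (`k_plus1` per chain length,
#' `k_minus1`, `k_plus2`), `temperature_C` and `enzyme_total_uM`. Unknown
#' keys are rejected. The named preset `"vhnag2"` carries the published
#' fitted VhNag2 parameter set.
#'
#' @param path File to read (`.yml`/`.yaml` or `.json`).
#'
#' @return A `model_config` list.
#' @export
#' @examples
#' cfg <- model_config_preset("vhnag2")
#' sys <- as_kinetic_system(cfg)
read_model_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "chitokin_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_model_config(cfg)
}

validate_model_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_sections)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", toString(unknown)),
          class = "chitokin_parse_error")
  }
  missing <- setdiff(config_sections, names(cfg))
  if (length(missing)) {
    abort(paste0("missing configuration section(s): ", toString(missing)),
          class = "chitokin_parse_error")
  }
  unknown_rates <- setdiff(names(cfg$rates), c("k_plus1", "k_minus1", "k_plus2"))
  if (length(unknown_rates)) {
    abort(paste0("unknown rate key(s): ", toString(unknown_rates)),
          class = "chitokin_parse_error")
  }
  structure(cfg, class = "model_config")
}

#' @rdname read_model_config
#' @param name Preset name; only `"vhnag2"` is defined.
#' @export
model_config_preset <- function(name = "vhnag2") {
  if (!identical(name, "vhnag2")) {
    abort(paste0("unknown preset: ", name), class = "chitokin_io_error")
  }
  validate_model_config(list(
    subsites = as.list(cleft_vhnag2()$energies),
    rates = list(
      k_plus1 = as.list(rate_constants()$k_plus1),
      k_minus1 = 0,
      k_plus2 = 50
    ),
    temperature_C = 30,
    enzyme_total_uM = 38
  ))
}

#' @rdname read_model_config
#' @param cfg A `model_config`.
#' @export
write_model_config <- function(cfg, path) {
  cfg <- validate_model_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

#' @rdname read_model_config
#' @export
as_kinetic_system <- function(cfg) {
  cfg <- validate_model_config(cfg)
  pos <- as.integer(names(cfg$subsites))
  o <- order(pos)
  cleft <- subsite_cleft(pos[o],
                         setNames(as.numeric(unlist(cfg$subsites))[o],
                                  as.character(pos[o])))
  k1 <- unlist(cfg$rates$k_plus1)
  kinetic_system(
    cleft = cleft,
    rates = rate_constants(k_plus1 = k1,
                           k_minus1 = cfg$rates$k_minus1 %||% 0,
                           k_plus2 = cfg$rates$k_plus2 %||% 50),
    temperature = rxn_temperature(cfg$temperature_C),
    enzyme_total_uM = cfg$enzyme_total_uM,
    max_chain = max(suppressWarnings(as.integer(names(k1))), length(cfg$subsites))
  )
}

#' Write a fit report as JSON
#'
#' Serialises a `subsite_fit` or `mm_fit` into a structured JSON report.
#'
#' @param fit The fitted object.
#' @param path Output file.
#'
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "subsite_fit")) {
    list(
      type = "subsite_fit",
      fitted_energies_kcal_mol = as.list(fit$fitted_energies),
      free_positions = fit$free_positions,
      final_cost_F_mM2 = fit$final_cost_F,
      iterations = fit$iterations,
      n_evals = fit$n_evals,
      converged = fit$converged
    )
  } else if (inherits(fit, "mm_fit")) {
    list(
      type = "mm_fit",
      Km_uM = fit$Km_uM,
      kcat_s = fit$kcat_s,
      kcat_over_Km_M_s = fit$kcat_over_Km,
      enzyme_total_uM = fit$enzyme_total_uM,
      se = as.list(fit$se)
    )
  } else {
    abort("`fit` must be a subsite_fit or mm_fit", class = "chitokin_io_error")
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
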