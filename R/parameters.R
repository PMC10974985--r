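# Receptor exposure parameters and reference doses for the EPA-style
# non-carcinogenic risk model.

exposure_parameter_names <- function() {
  c(
    "ingestion_rate", "skin_area", "skin_adherence", "dermal_absorption",
    "inhalation_rate", "particle_emission_factor", "exposure_frequency",
    "exposure_duration", "body_weight", "averaging_time_noncarcinogenic",
    "averaging_time_carcinogenic", "conversion_factor", "volatilization_factor"
  )
}

exposure_defaults <- function(receptor) {
  switch(receptor,
    child = list(
      ingestion_rate = 200,              # IngR, mg/day
      skin_area = 2800,                  # SA, cm^2
      skin_adherence = 0.2,              # AF (the "SL" slot of the dermal dose), mg/cm^2
      dermal_absorption = 0.001,         # ABS, unitless
      inhalation_rate = 7.6,             # InhR, m^3/day
      particle_emission_factor = 1.4e9,  # PEF, m^3/kg
      exposure_frequency = 285,          # days/year
      exposure_duration = 6,             # years
      body_weight = 15,                  # kg
      averaging_time_noncarcinogenic = 2190,   # days = ED * 365
      averaging_time_carcinogenic = 25550,     # days (stored, unused)
      conversion_factor = 1e-6,          # kg/mg
      volatilization_factor = 32675.6    # m^3/kg (stored, unused)
    ),
    adult = list(
      ingestion_rate = 100,
      skin_area = 5700,
      skin_adherence = 0.7,
      dermal_absorption = 0.001,
      inhalation_rate = 20,
      particle_emission_factor = 1.4e9,
      exposure_frequency = 285,
      exposure_duration = 30,
      body_weight = 70,
      averaging_time_noncarcinogenic = 10950,
      averaging_time_carcinogenic = 25550,
      conversion_factor = 1e-6,
      volatilization_factor = 32675.6
    ),
    stopf("unknown receptor '%s' (use 'child' or 'adult')", receptor)
  )
}

#' Receptor exposure parameters
#'
#' Returns the exposure constants used by the dose equations for one
#' receptor. Defaults are the standard child/adult dust-exposure parameter
#' set (ingestion rate 200/100 mg/day, skin area 2800/5700 cm^2, skin
#' adherence 0.2/0.7 mg/cm^2, dermal absorption 0.001, inhalation rate
#' 7.6/20 m^3/day, particle emission factor 1.4e9 m^3/kg, exposure frequency
#' 285 days/year, exposure duration 6/30 years, body weight 15/70 kg).
#' The non-carcinogenic averaging time is always `exposure_duration * 365`
#' days; overriding `exposure_duration` recomputes it unless an explicit
#' consistent value is also supplied. The carcinogenic averaging time and
#' the volatilization factor are stored for completeness but consumed by no
#' computation (the risk model here is non-carcinogenic only).
#'
#' Note on naming: "exposure_frequency" is always spelled out — the
#' enrichment factor (a pollution index) is an unrelated quantity and is
#' named `enrichment_factor()`.
#'
#' @param receptor `"child"` or `"adult"`.
#' @param ... named overrides of individual parameters (see
#'   `exposure_parameter_names()`).
#' @return an object of class `"exposure_parameters"` (a named list).
#' @examples
#' exposure_parameters("child")$ingestion_rate # 200
#' @export
exposure_parameters <- function(receptor = c("child", "adult"), ...) {
  receptor <- match.arg(receptor)
  params <- exposure_defaults(receptor)
  overrides <- list(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), exposure_parameter_names())
    if (length(unknown) > 0L || is.null(names(overrides)) || any(names(overrides) == "")) {
      stopf("unknown exposure parameter(s): %s\nvalid keys: %s",
            paste(unknown, collapse = ", "),
            paste(exposure_parameter_names(), collapse = ", "))
    }
    at_given <- "averaging_time_noncarcinogenic" %in% names(overrides)
    params[names(overrides)] <- lapply(overrides, as.numeric)
    if (!at_given) {
      params$averaging_time_noncarcinogenic <- params$exposure_duration * 365
    }
  }
  vals <- unlist(params)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stopf("exposure parameters must be finite and > 0 (offending: %s)",
          paste(bad, collapse = ", "))
  }
  if (abs(params$averaging_time_noncarcinogenic - params$exposure_duration * 365) >
      1e-9 * params$averaging_time_noncarcinogenic) {
    stopf("averaging_time_noncarcinogenic (%g) must equal exposure_duration * 365 (%g)",
          params$averaging_time_noncarcinogenic, params$exposure_duration * 365)
  }
  structure(c(list(receptor = receptor), params), class = "exposure_parameters")
}

#' @export
print.exposure_parameters <- function(x, ...) {
  cat(sprintf("Exposure parameters (%s receptor):\n", x$receptor))
  for (nm in exposure_parameter_names()) {
    cat(sprintf("  %-32s %g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Reference-dose (RfD) table
#'
#' The default table carries the per-pathway reference doses in
#' mg/(kg*day) used by the hazard model: As, Cu, Zn, Zr, Sr, Pb, Cr, V and
#' Fe. Zr has an ingestion entry only (dermal and inhalation are
#' unavailable, encoded `NA`); Sc and Rb have no entries at all and are
#' therefore skipped — with a warning — by [hazard_index()].
#'
#' @param table optional data.frame with columns `element`, `ingestion`,
#'   `dermal`, `inhalation` to validate instead of the packaged defaults;
#'   `NA` marks an unavailable pathway.
#' @return data.frame of class `"rfd_table"` with rownames = elements.
#' @examples
#' rfd_table()["As", "ingestion"] # 3e-04
#' @export
rfd_table <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      element = c("As", "Cu", "Zn", "Zr", "Sr", "Pb", "Cr", "V", "Fe"),
      ingestion = c(0.0003, 0.04, 0.3, 0.00008, 0.6, 0.0035, 1.5, 0.007, 0.7),
      dermal = c(0.000123, 0.0402, 0.3, NA, 0.12, 0.00053, 0.006, 0.007, 0.7),
      inhalation = c(0.000301, 0.012, 0.35, NA, 0.6, 0.0035, 0.00003, 0.00007, 0.8),
      stringsAsFactors = FALSE
    )
  }
  required <- c("element", "ingestion", "dermal", "inhalation")
  if (!all(required %in% names(table))) {
    stopf("RfD table must have columns: %s", paste(required, collapse = ", "))
  }
  table <- table[, required]
  if (anyDuplicated(table$element)) stopf("duplicate elements in RfD table")
  for (pw in c("ingestion", "dermal", "inhalation")) {
    v <- table[[pw]]
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad)) {
      stopf("RfD values must be > 0 when present (offending: %s, %s)",
            table$element[bad][1L], pw)
    }
  }
  rownames(table) <- table$element
  class(table) <- c("rfd_table", "data.frame")
  table
}
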