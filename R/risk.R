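# Non-carcinogenic health-risk model: average daily doses over three
# exposure pathways, hazard quotients against reference doses, and the
# hazard index with its risk threshold at 1.

#' Average daily dose (ADD) for one exposure pathway
#'
#' Doses in mg/(kg*day) for a receptor exposed to dust with concentration
#' `conc` (mg/kg):
#' \describe{
#'   \item{ingestion}{`C * IngR * EFfreq * ED / (BW * AT) * CFconv`}
#'   \item{inhalation}{`C * InhR * EFfreq * ED / (PEF * BW * AT)`}
#'   \item{dermal}{`C * AF * SA * ABS * EFfreq * ED / (BW * AT) * CFconv`}
#' }
#' where IngR/InhR are the ingestion/inhalation rates, EFfreq the exposure
#' frequency, ED the exposure duration, BW body weight, AT the
#' non-carcinogenic averaging time, PEF the particle emission factor, AF
#' the skin adherence factor, SA the exposed skin area, ABS the dermal
#' absorption fraction and CFconv the kg/mg conversion (1e-6). All doses
#' are linear in concentration and zero at zero concentration.
#'
#' Some published statements of the inhalation dose reuse the ingestion
#' rate symbol in the numerator; that is inconsistent with a separately
#' tabulated inhalation rate and is treated here as a typographical slip.
#' Set `inhalation_rate_source = "ingestion_rate"` to reproduce the
#' literal-printed variant for sensitivity checks.
#'
#' @param conc numeric vector or matrix of concentrations, mg/kg.
#' @param params an [exposure_parameters()] object.
#' @param pathway one of `"ingestion"`, `"inhalation"`, `"dermal"`.
#' @param inhalation_rate_source which parameter feeds the inhalation dose
#'   numerator; default the inhalation rate.
#' @return doses with the shape of `conc`, mg/(kg*day).
#' @examples
#' average_daily_dose(100, exposure_parameters("child"), "ingestion")
#' @export
average_daily_dose <- function(conc, params,
                               pathway = c("ingestion", "inhalation", "dermal"),
                               inhalation_rate_source = c("inhalation_rate", "ingestion_rate")) {
  pathway <- match.arg(pathway)
  inhalation_rate_source <- match.arg(inhalation_rate_source)
  stopifnot(inherits(params, "exposure_parameters"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stopf("concentrations must be finite and >= 0")
  }
  p <- params
  core <- p$exposure_frequency * p$exposure_duration /
    (p$body_weight * p$averaging_time_noncarcinogenic)
  switch(pathway,
    ingestion = conc * p$ingestion_rate * core * p$conversion_factor,
    inhalation = conc * p[[inhalation_rate_source]] * core / p$particle_emission_factor,
    dermal = conc * p$skin_adherence * p$skin_area * p$dermal_absorption *
      core * p$conversion_factor
  )
}

#' Hazard quotient (HQ)
#'
#' `HQ = ADD / RfD` for one pathway. An HQ at or above 1 means the dose
#' meets or exceeds the reference dose presumed safe.
#'
#' @param add average daily dose, mg/(kg*day).
#' @param rfd reference dose, mg/(kg*day); must be > 0.
#' @return dimensionless hazard quotient(s).
#' @export
hazard_quotient <- function(add, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stopf("RfD must be finite and > 0 (missing pathways are skipped upstream)")
  }
  if (any(!is.finite(add)) || any(add < 0)) stopf("ADD must be finite and >= 0")
  add / rfd
}

#' Hazard index (HI) across exposure pathways
#'
#' For each site and element with at least one reference dose, computes the
#' pathway doses, the hazard quotients for the pathways whose RfD is
#' available, and their sum, the hazard index. Elements without any RfD
#' entry (e.g. Sc and Rb under the default table) are excluded with a
#' warning; a pathway whose RfD is unavailable (Zr dermal/inhalation)
#' contributes nothing to the HI and its HQ is reported as `NA`. The risk
#' flag marks HI >= 1.
#'
#' @param conc a [concentration_matrix()].
#' @param params an [exposure_parameters()] object.
#' @param rfd an [rfd_table()]; defaults to the packaged table.
#' @param inhalation_rate_source passed to [average_daily_dose()].
#' @return data.frame with columns `site, element, receptor,
#'   add_ingestion, add_inhalation, add_dermal, hq_ingestion,
#'   hq_inhalation, hq_dermal, hi, risk_flag`.
#' @export
hazard_index <- function(conc, params, rfd = rfd_table(),
                         inhalation_rate_source = c("inhalation_rate", "ingestion_rate")) {
  conc <- concentration_matrix(conc)
  inhalation_rate_source <- match.arg(inhalation_rate_source)
  stopifnot(inherits(params, "exposure_parameters"), inherits(rfd, "rfd_table"))

  skipped <- setdiff(colnames(conc), rownames(rfd))
  if (length(skipped) > 0L) {
    warnf("element(s) without reference doses excluded from hazard index: %s",
          paste(skipped, collapse = ", "))
  }
  elements <- intersect(colnames(conc), rownames(rfd))
  if (length(elements) == 0L) stopf("no element in the input has a reference dose")

  pathways <- c("ingestion", "inhalation", "dermal")
  out <- do.call(rbind, lapply(elements, function(el) {
    c_el <- unclass(conc)[, el]
    adds <- lapply(pathways, function(pw) {
      average_daily_dose(c_el, params, pw, inhalation_rate_source)
    })
    names(adds) <- pathways
    hqs <- lapply(pathways, function(pw) {
      r <- rfd[el, pw]
      if (is.na(r)) rep(NA_real_, length(c_el)) else hazard_quotient(adds[[pw]], r)
    })
    names(hqs) <- pathways
    hi <- rowSums(cbind(hqs$ingestion, hqs$inhalation, hqs$dermal), na.rm = TRUE)
    data.frame(
      site = rownames(conc), element = el, receptor = params$receptor,
      add_ingestion = adds$ingestion, add_inhalation = adds$inhalation,
      add_dermal = adds$dermal,
      hq_ingestion = hqs$ingestion, hq_inhalation = hqs$inhalation,
      hq_dermal = hqs$dermal,
      hi = hi, risk_flag = hi >= 1,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  rownames(out) <- NULL
  out
}

#' Ranked hazard report
#'
#' Sorts a [hazard_index()] result by HI (descending, per receptor) and
#' extracts the site/element pairs whose hazard index meets or exceeds 1.
#'
#' @param hazard data.frame as returned by [hazard_index()] (results for
#'   several receptors may be row-bound).
#' @return list with `ranked` (full table, HI descending within receptor)
#'   and `flagged` (subset with `hi >= 1`).
#' @export
risk_report <- function(hazard) {
  if (!is.data.frame(hazard) || nrow(hazard) == 0L) {
    stopf("risk_report requires a nonempty hazard_index result")
  }
  ranked <- hazard[order(hazard$receptor, -hazard$hi), , drop = FALSE]
  rownames(ranked) <- NULL
  flagged <- ranked[ranked$hi >= 1, , drop = FALSE]
  rownames(flagged) <- NULL
  list(ranked = ranked, flagged = flagged)
}
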