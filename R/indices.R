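# Contamination indices for site-by-element concentration data.
#
# All per-element indices return a tidy data.frame
#   site, element, index, value, class
# and all site-level indices return
#   site, index, value, class
# so results concatenate cleanly into the output CSVs.

index_row <- function(site, element, index, value, class) {
  data.frame(site = site, element = element, index = index,
             value = value, class = class, stringsAsFactors = FALSE)
}

#' Classify a geo-accumulation index value
#'
#' Mueller's seven classes: class 0 for Igeo <= 0, then unit-wide bins
#' (k-1, k] up to class 5, and class 6 for Igeo > 5. Undefined values
#' (`NA`, from a zero concentration) fall in class 0.
#'
#' @param igeo numeric vector of Igeo values (NA allowed).
#' @return character vector of class labels.
#' @export
classify_igeo <- function(igeo) {
  labels <- c(
    "class 0 (unpolluted)",
    "class 1 (unpolluted to moderately polluted)",
    "class 2 (moderately polluted)",
    "class 3 (moderately to heavily polluted)",
    "class 4 (heavily polluted)",
    "class 5 (heavily to extremely polluted)",
    "class 6 (extremely polluted)"
  )
  idx <- pmin(pmax(ceiling(igeo), 0), 6)
  idx[is.na(igeo)] <- 0
  labels[idx + 1L]
}

#' Geo-accumulation index (Igeo)
#'
#' `Igeo = log2(Cn / (1.5 * Bn))` per site and element, where Bn is the
#' geochemical background and the factor 1.5 absorbs natural background
#' variation. A zero concentration makes the logarithm undefined; the value
#' is reported as `NA` with class 0.
#'
#' @param conc a [concentration_matrix()].
#' @param background named background vector (mg/kg), one entry per element
#'   of `conc`.
#' @return tidy data.frame `site, element, index, value, class`.
#' @examples
#' cm <- concentration_matrix(matrix(c(75, 150), 1,
#'   dimnames = list("S1", c("Pb", "Zn"))))
#' geo_accumulation_index(cm, c(Pb = 50, Zn = 50))
#' @export
geo_accumulation_index <- function(conc, background) {
  conc <- concentration_matrix(conc)
  bn <- align_background(conc, background)
  ratio <- sweep(unclass(conc), 2L, 1.5 * bn, "/")
  igeo <- suppressWarnings(log2(ratio))
  igeo[unclass(conc) == 0] <- NA_real_ # log of zero: flagged undefined
  index_row(
    site = rep(rownames(conc), times = ncol(conc)),
    element = rep(colnames(conc), each = nrow(conc)),
    index = "igeo",
    value = as.vector(igeo),
    class = classify_igeo(as.vector(igeo))
  )
}

#' Classify a contamination factor
#'
#' Low below 1, moderate in `[1, 3)`, considerable in `[3, 6]`, very high
#' above 6. The bins are lower-inclusive; CF exactly 6 is classified
#' "considerable" (the boundary treatment is a package convention — the
#' scheme's published wording does not resolve the exact boundaries).
#'
#' @param cf numeric vector of contamination factors.
#' @return character vector of class labels.
#' @export
classify_cf <- function(cf) {
  ifelse(cf < 1, "low contamination",
    ifelse(cf < 3, "moderate contamination",
      ifelse(cf <= 6, "considerable contamination", "very high contamination")))
}

#' Contamination factor (CF)
#'
#' `CF = C_sample / C_background` per site and element.
#'
#' @inheritParams geo_accumulation_index
#' @return tidy data.frame `site, element, index, value, class`.
#' @export
contamination_factor <- function(conc, background) {
  conc <- concentration_matrix(conc)
  bn <- align_background(conc, background)
  cf <- sweep(unclass(conc), 2L, bn, "/")
  index_row(
    site = rep(rownames(conc), times = ncol(conc)),
    element = rep(colnames(conc), each = nrow(conc)),
    index = "cf",
    value = as.vector(cf),
    class = classify_cf(as.vector(cf))
  )
}

# internal: site x element CF matrix
cf_matrix <- function(conc, background) {
  conc <- concentration_matrix(conc)
  sweep(unclass(conc), 2L, align_background(conc, background), "/")
}

#' Classify a modified degree of contamination
#' @param mcd numeric vector of mCd values.
#' @return character vector of class labels.
#' @export
classify_mcd <- function(mcd) {
  ifelse(mcd <= 1.5, "uncontaminated to very low",
    ifelse(mcd <= 2, "low",
      ifelse(mcd <= 4, "moderate",
        ifelse(mcd <= 8, "high",
          ifelse(mcd <= 16, "very high",
            ifelse(mcd <= 32, "extremely high", "ultra-high"))))))
}

#' Modified degree of contamination (mCd) for one site
#'
#' The arithmetic mean of a site's contamination factors over the measured
#' elements.
#'
#' @param cf numeric vector of contamination factors for one site.
#' @return single-row data.frame `index, value, class`.
#' @examples
#' modified_degree_of_contamination(c(1, 2, 3)) # mCd = 2, "low"
#' @export
modified_degree_of_contamination <- function(cf) {
  if (length(cf) == 0L) stopf("mCd of an empty CF set is undefined")
  if (any(!is.finite(cf))) stopf("mCd requires finite CF values")
  value <- mean(cf)
  data.frame(index = "mcd", value = value, class = classify_mcd(value),
             stringsAsFactors = FALSE)
}

#' Classify a pollution load index value
#' @param pli numeric vector of PLI values.
#' @return character vector of interpretation labels.
#' @export
classify_pli <- function(pli) {
  ifelse(pli < 1, "no pollution",
    ifelse(pli == 1, "baseline levels of pollutants", "deteriorated"))
}

#' Pollution load index (PLI) for one site
#'
#' Geometric mean of a site's contamination factors, computed in log space.
#' All CFs must be strictly positive (geometric mean of a zero is
#' undefined, so zero concentrations must be excluded upstream).
#'
#' @param cf numeric vector of contamination factors for one site.
#' @return single-row data.frame `index, value, class`.
#' @examples
#' pollution_load_index_site(c(4, 1)) # PLI = 2
#' @export
pollution_load_index_site <- function(cf) {
  if (length(cf) == 0L) stopf("PLI of an empty CF set is undefined")
  if (any(!is.finite(cf)) || any(cf <= 0)) {
    stopf("PLI requires strictly positive CF values (geometric mean undefined otherwise)")
  }
  value <- geometric_mean(cf)
  data.frame(index = "pli", value = value, class = classify_pli(value),
             stringsAsFactors = FALSE)
}

#' Pollution load index for a zone
#'
#' Geometric mean of the site PLIs of the zone.
#'
#' @param site_plis numeric vector of site-level PLI values.
#' @return single-row data.frame `index, value, class`.
#' @export
pollution_load_index_zone <- function(site_plis) {
  if (length(site_plis) == 0L) stopf("zone PLI of an empty site set is undefined")
  if (any(!is.finite(site_plis)) || any(site_plis <= 0)) {
    stopf("zone PLI requires strictly positive site PLIs")
  }
  value <- geometric_mean(site_plis)
  data.frame(index = "pli_zone", value = value, class = classify_pli(value),
             stringsAsFactors = FALSE)
}

#' Site-level contamination summary (mCd and PLI per site, zone PLI)
#'
#' Convenience wrapper that computes the contamination-factor matrix and
#' derives the site-level indices. By default all elements present in the
#' input enter the mCd and PLI; `elements` restricts the set.
#'
#' @inheritParams geo_accumulation_index
#' @param elements optional character vector restricting which elements
#'   enter the site-level indices.
#' @return data.frame `site, index, value, class`, with one final
#'   `site = "zone"` row carrying the zone PLI.
#' @export
site_contamination_summary <- function(conc, background, elements = NULL) {
  cf <- cf_matrix(conc, background)
  if (!is.null(elements)) {
    missing <- setdiff(elements, colnames(cf))
    if (length(missing) > 0L) {
      stopf("element(s) not in concentration matrix: %s", paste(missing, collapse = ", "))
    }
    cf <- cf[, elements, drop = FALSE]
  }
  rows <- do.call(rbind, lapply(rownames(cf), function(s) {
    rbind(
      cbind(site = s, modified_degree_of_contamination(cf[s, ])),
      cbind(site = s, pollution_load_index_site(cf[s, ]))
    )
  }))
  plis <- rows$value[rows$index == "pli"]
  rbind(rows, cbind(site = "zone", pollution_load_index_zone(plis)))
}

#' Classify an enrichment factor
#'
#' Below 1: no enrichment. Between 1 and 3 (inclusive): consistent with
#' natural weathering. Above 3: significant non-crustal (anthropogenic)
#' contribution. Above 50: extremely severe enrichment.
#'
#' @param ef numeric vector of enrichment factors.
#' @return character vector of class labels.
#' @export
classify_ef <- function(ef) {
  ifelse(ef < 1, "no enrichment",
    ifelse(ef <= 3, "natural weathering",
      ifelse(ef <= 50, "significant non-crustal contribution",
        "extremely severe enrichment")))
}

#' Enrichment factor (EF) with a crustal reference element
#'
#' `EF = (Cx/Cref)_sample / (Cx/Cref)_background` per site and element,
#' with iron as the default crustal reference. The reference element's EF
#' is 1 by construction at every site.
#'
#' @inheritParams geo_accumulation_index
#' @param reference_element symbol of the crustal reference element
#'   (default `"Fe"`); must be present in `conc` and `background` with
#'   strictly positive values.
#' @return tidy data.frame `site, element, index, value, class`.
#' @export
enrichment_factor <- function(conc, background, reference_element = "Fe") {
  conc <- concentration_matrix(conc)
  bn <- align_background(conc, background)
  if (!reference_element %in% colnames(conc)) {
    stopf("reference element %s not present in concentration matrix", reference_element)
  }
  ref_conc <- unclass(conc)[, reference_element]
  zero_ref <- which(ref_conc == 0)
  if (length(zero_ref) > 0L) {
    stopf("reference element %s has zero concentration at site %s",
          reference_element, rownames(conc)[zero_ref[1L]])
  }
  sample_ratio <- sweep(unclass(conc), 1L, ref_conc, "/")
  background_ratio <- bn / bn[reference_element]
  ef <- sweep(sample_ratio, 2L, background_ratio, "/")
  index_row(
    site = rep(rownames(conc), times = ncol(conc)),
    element = rep(colnames(conc), each = nrow(conc)),
    index = "ef",
    value = as.vector(ef),
    class = classify_ef(as.vector(ef))
  )
}

#' Construct and validate a PM time series
#'
#' @param timestamps strictly increasing vector (Date, POSIXct, or numeric).
#' @param pm25,pm10 non-negative concentrations in ug/m^3, same length as
#'   `timestamps`.
#' @return data.frame of class `"pm_series"`.
#' @export
pm_series <- function(timestamps, pm25, pm10) {
  if (length(timestamps) != length(pm25) || length(pm25) != length(pm10)) {
    stopf("timestamps, pm25 and pm10 must have equal lengths")
  }
  if (length(timestamps) == 0L) stopf("empty PM series")
  if (any(diff(as.numeric(timestamps)) <= 0)) {
    stopf("timestamps must be strictly increasing")
  }
  if (any(!is.finite(pm25)) || any(pm25 < 0) || any(!is.finite(pm10)) || any(pm10 < 0)) {
    stopf("PM values must be finite and >= 0")
  }
  structure(
    data.frame(timestamp = timestamps, pm25 = pm25, pm10 = pm10),
    class = c("pm_series", "data.frame")
  )
}

#' Read a PM CSV (`timestamp,pm25,pm10`)
#'
#' @param path path to a CSV file.
#' @return a [pm_series()].
#' @export
read_pm_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "pm25", "pm10") %in% names(df))) {
    stopf("PM CSV must have columns timestamp, pm25, pm10")
  }
  ts <- df$timestamp
  if (is.character(ts)) {
    parsed <- as.Date(ts)
    if (!any(is.na(parsed))) ts <- parsed
  }
  pm_series(ts, df$pm25, df$pm10)
}

#' PM2.5/PM10 ratio summary
#'
#' The fine-to-coarse particulate ratio is a source indicator: low ratios
#' point to coarse, crustal/mechanical particles; ratios above 0.5 are
#' considered high and combustion-dominated. Ratios are undefined where
#' PM10 is zero (excluded from the summary with a warning); timestamps
#' where PM2.5 exceeds PM10 are physically suspect and flagged but kept.
#'
#' @param series a [pm_series()].
#' @return list with `ratios` (data.frame `timestamp, ratio,
#'   combustion_dominated, pm25_exceeds_pm10`), and `mean`, `min`, `max`,
#'   `n_undefined` summary fields.
#' @export
pm_ratio_summary <- function(series) {
  stopifnot(inherits(series, "pm_series"))
  ratio <- ifelse(series$pm10 > 0, series$pm25 / series$pm10, NA_real_)
  n_undef <- sum(is.na(ratio))
  if (n_undef > 0L) {
    warnf("%d timestamp(s) with PM10 = 0: ratio undefined, excluded from summary", n_undef)
  }
  exceeds <- !is.na(ratio) & series$pm25 > series$pm10
  if (any(exceeds)) {
    warnf("%d timestamp(s) with PM2.5 > PM10 (flagged, not dropped)", sum(exceeds))
  }
  ratios <- data.frame(
    timestamp = series$timestamp,
    ratio = ratio,
    combustion_dominated = !is.na(ratio) & ratio > 0.5,
    pm25_exceeds_pm10 = exceeds
  )
  ok <- ratio[!is.na(ratio)]
  list(
    ratios = ratios,
    mean = if (length(ok)) mean(ok) else NA_real_,
    min = if (length(ok)) min(ok) else NA_real_,
    max = if (length(ok)) max(ok) else NA_real_,
    n_undefined = n_undef
  )
}
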