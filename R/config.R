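# Plain-text key-value configuration.
#
# Format: INI-style sections. Lines are `key = value`; `#` or `;` start
# comments; blank lines ignored. Recognised sections:
#   [child], [adult]   exposure-parameter overrides (keys as in
#                      exposure_parameter_names())
#   [rfd]              keys <Element>_<pathway>, e.g. As_ingestion = 0.0003;
#                      value "-" or "NA" removes a pathway entry
#   [background]       keys are element symbols, values mg/kg
#   [pmf]              k_candidates (comma list), n_starts, max_iter, tol
#   [synthetic]        n_sites, k_true, noise_cv, seed
#   [options]          inhalation_uses_ingestion_rate = true/false (the
#                      literal-printed dose variant), index_elements
#                      (comma list restricting mCd/PLI)

parse_config_lines <- function(lines) {
  section <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("[#;].*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stopf("config line %d is neither a [section] nor a key = value pair: '%s'",
            i, lines[i])
    }
    if (is.na(section)) {
      stopf("config line %d appears before any [section] header", i)
    }
    key <- trimws(sub("=.*$", "", line))
    value <- trimws(sub("^[^=]*=", "", line))
    out[[section]][[key]] <- value
  }
  out
}

config_sections <- function() {
  c("child", "adult", "rfd", "background", "pmf", "synthetic", "options")
}

#' Load run configuration from a plain-text key-value file
#'
#' Absent sections and keys fall back to the packaged defaults (the child
#' and adult exposure-parameter sets, the reference-dose table, and the
#' world-soil median background). Provenance — which values came from the
#' file and which from defaults — is recorded in the `provenance` element
#' and reported via `message()`.
#'
#' @param path path to a config file, or `NULL` for pure defaults.
#' @param quiet suppress the provenance message.
#' @return a list with elements `child`, `adult` (exposure_parameters),
#'   `rfd` (rfd_table), `background` (named vector), `pmf`, `synthetic`,
#'   `options` (lists), and `provenance` (character vector of overridden
#'   keys, empty when everything is a default).
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    raw <- parse_config_lines(readLines(path, warn = FALSE))
    unknown <- setdiff(names(raw), config_sections())
    if (length(unknown) > 0L) {
      stopf("unknown config section(s): %s\nvalid sections: %s",
            paste(unknown, collapse = ", "),
            paste(config_sections(), collapse = ", "))
    }
  }
  provenance <- character(0)

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stopf("config value for %s is not numeric: '%s'", what, x)
    v
  }

  # receptors
  receptors <- list()
  for (rec in c("child", "adult")) {
    overrides <- raw[[rec]]
    if (length(overrides) > 0L) {
      unknown <- setdiff(names(overrides), exposure_parameter_names())
      if (length(unknown) > 0L) {
        stopf("unknown key(s) in [%s]: %s\nvalid keys: %s", rec,
              paste(unknown, collapse = ", "),
              paste(exposure_parameter_names(), collapse = ", "))
      }
      vals <- lapply(overrides, num, what = rec)
      receptors[[rec]] <- do.call(exposure_parameters, c(list(receptor = rec), vals))
      provenance <- c(provenance, paste0(rec, ".", names(overrides)))
    } else {
      receptors[[rec]] <- exposure_parameters(rec)
    }
  }

  # rfd
  rfd <- rfd_table()
  if (length(raw$rfd) > 0L) {
    for (key in names(raw$rfd)) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[2L] %in% c("ingestion", "dermal", "inhalation")) {
        stopf("unknown key in [rfd]: %s\nvalid keys look like As_ingestion, Zr_dermal", key)
      }
      el <- parts[1L]; pw <- parts[2L]
      val <- raw$rfd[[key]]
      if (!el %in% rownames(rfd)) {
        rfd[el, "element"] <- el
        rownames(rfd)[nrow(rfd)] <- el
      }
      rfd[el, pw] <- if (val %in% c("-", "NA", "na")) NA_real_ else num(val, key)
      provenance <- c(provenance, paste0("rfd.", key))
    }
    rfd <- rfd_table(as.data.frame(rfd))
  }

  # background
  background <- default_background()
  if (length(raw$background) > 0L) {
    for (el in names(raw$background)) {
      background[el] <- num(raw$background[[el]], paste0("background.", el))
      provenance <- c(provenance, paste0("background.", el))
    }
    background <- background_table(background)
  }

  # pmf
  pmf <- list(k_candidates = 3:5, n_starts = 20L, max_iter = 5000L, tol = 1e-8)
  if (length(raw$pmf) > 0L) {
    unknown <- setdiff(names(raw$pmf), names(pmf))
    if (length(unknown) > 0L) {
      stopf("unknown key(s) in [pmf]: %s\nvalid keys: %s",
            paste(unknown, collapse = ", "), paste(names(pmf), collapse = ", "))
    }
    for (key in names(raw$pmf)) {
      val <- raw$pmf[[key]]
      pmf[[key]] <- if (key == "k_candidates") {
        as.integer(vapply(strsplit(val, ",")[[1L]], num, numeric(1L), what = key))
      } else if (key == "tol") num(val, key) else as.integer(num(val, key))
      provenance <- c(provenance, paste0("pmf.", key))
    }
  }

  # synthetic
  synth <- list(n_sites = 24L, k_true = 5L, noise_cv = 0.10, seed = 1L)
  if (length(raw$synthetic) > 0L) {
    unknown <- setdiff(names(raw$synthetic), names(synth))
    if (length(unknown) > 0L) {
      stopf("unknown key(s) in [synthetic]: %s\nvalid keys: %s",
            paste(unknown, collapse = ", "), paste(names(synth), collapse = ", "))
    }
    for (key in names(raw$synthetic)) {
      v <- num(raw$synthetic[[key]], key)
      synth[[key]] <- if (key == "noise_cv") v else as.integer(v)
      provenance <- c(provenance, paste0("synthetic.", key))
    }
  }

  # options
  opts <- list(inhalation_uses_ingestion_rate = FALSE, index_elements = NULL)
  if (length(raw$options) > 0L) {
    unknown <- setdiff(names(raw$options), names(opts))
    if (length(unknown) > 0L) {
      stopf("unknown key(s) in [options]: %s\nvalid keys: %s",
            paste(unknown, collapse = ", "), paste(names(opts), collapse = ", "))
    }
    if (!is.null(raw$options$inhalation_uses_ingestion_rate)) {
      opts$inhalation_uses_ingestion_rate <-
        tolower(raw$options$inhalation_uses_ingestion_rate) %in% c("true", "yes", "1")
      provenance <- c(provenance, "options.inhalation_uses_ingestion_rate")
    }
    if (!is.null(raw$options$index_elements)) {
      opts$index_elements <- trimws(strsplit(raw$options$index_elements, ",")[[1L]])
      provenance <- c(provenance, "options.index_elements")
    }
  }

  if (!quiet) {
    if (length(provenance) > 0L) {
      message("config: ", length(provenance), " value(s) from file (",
              paste(provenance, collapse = ", "), "); all others defaults")
    } else {
      message("config: all values from packaged defaults")
    }
  }

  list(child = receptors$child, adult = receptors$adult, rfd = rfd,
       background = background, pmf = pmf, synthetic = synth,
       options = opts, provenance = provenance)
}
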