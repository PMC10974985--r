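# Concentration matrices and background tables: the central data containers.

#' The eleven element symbols measured in the school-dust study design
#'
#' Order matches the canonical concentration CSV header
#' `site,As,Cu,Zn,Zr,Sr,Rb,Pb,Cr,V,Fe,Sc`.
#'
#' @return character vector of element symbols.
#' @export
dust_elements <- function() {
  c("As", "Cu", "Zn", "Zr", "Sr", "Rb", "Pb", "Cr", "V", "Fe", "Sc")
}

#' Construct a validated site-by-element concentration matrix
#'
#' A concentration matrix holds dust concentrations in mg/kg dry dust, one
#' row per sampling site and one column per chemical element. Values must be
#' finite and non-negative; site and element identifiers must be unique and
#' non-empty. Zeros are accepted (they trigger documented behaviour in the
#' index functions, e.g. an undefined geo-accumulation index).
#'
#' @param values numeric matrix (or object coercible to one) of
#'   concentrations in mg/kg.
#' @param site_ids character vector of unique site identifiers; defaults to
#'   the rownames of `values`.
#' @param element_symbols character vector of unique element symbols;
#'   defaults to the colnames of `values`.
#' @return a numeric matrix of class `"concentration_matrix"` with sites as
#'   rownames and elements as colnames.
#' @examples
#' concentration_matrix(matrix(c(10, 30, 20, 40), 2, 2,
#'   dimnames = list(c("S1", "S2"), c("Pb", "Zn"))))
#' @export
concentration_matrix <- function(values, site_ids = rownames(values),
                                 element_symbols = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stopf("concentration values must be numeric")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stopf("concentration matrix must have at least one site and one element")
  }
  if (is.null(site_ids)) {
    site_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(element_symbols)) {
    stopf("element symbols are required (column names)")
  }
  site_ids <- as.character(site_ids)
  element_symbols <- as.character(element_symbols)
  if (length(site_ids) != nrow(values)) {
    stopf("length of site_ids (%d) does not match number of rows (%d)",
          length(site_ids), nrow(values))
  }
  if (length(element_symbols) != ncol(values)) {
    stopf("length of element_symbols (%d) does not match number of columns (%d)",
          length(element_symbols), ncol(values))
  }
  if (anyDuplicated(site_ids)) {
    stopf("duplicate site ids: %s",
          paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  }
  if (anyDuplicated(element_symbols)) {
    stopf("duplicate element symbols: %s",
          paste(unique(element_symbols[duplicated(element_symbols)]), collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("invalid concentration (negative or non-finite) at site %s, element %s",
          site_ids[bad[1L, 1L]], element_symbols[bad[1L, 2L]])
  }
  dimnames(values) <- list(site_ids, element_symbols)
  class(values) <- c("concentration_matrix", class(matrix()))
  values
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat(sprintf("Concentration matrix: %d sites x %d elements (mg/kg)\n",
              nrow(x), ncol(x)))
  y <- x
  class(y) <- NULL
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more sites\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a concentration CSV
#'
#' Expected dialect: a header row whose first field is the site-id column
#' (conventionally `site`) followed by element symbols, then one row per
#' site with concentrations in mg/kg.
#'
#' @param path path to a CSV file.
#' @return a [concentration_matrix()].
#' @seealso [write_concentration_csv()]
#' @export
read_concentration_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("concentration CSV needs a site column plus element columns")
  headers <- names(df)
  if (any(is.na(headers)) || any(headers == "")) {
    stopf("concentration CSV has missing column headers")
  }
  if (anyDuplicated(headers)) {
    stopf("concentration CSV has duplicate column headers: %s",
          paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  sites <- as.character(df[[1L]])
  elements <- headers[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (is.numeric(vals)) storage.mode(vals) <- "double"
  if (!is.numeric(vals)) {
    # find first offending cell for a precise message
    for (j in seq_along(elements)) {
      col <- suppressWarnings(as.numeric(df[[j + 1L]]))
      bad <- which(is.na(col) & !is.na(df[[j + 1L]]))
      if (length(bad) > 0L) {
        stopf("non-numeric concentration at site %s, element %s",
              sites[bad[1L]], elements[j])
      }
    }
    stopf("non-numeric concentration values in %s", path)
  }
  concentration_matrix(vals, site_ids = sites, element_symbols = elements)
}

#' Write a concentration CSV
#'
#' Values are written with 12 significant digits so that
#' `read_concentration_csv(write_concentration_csv(x))` round-trips losslessly
#' for values representable at that precision.
#'
#' @param x a [concentration_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(x, path) {
  x <- concentration_matrix(x)
  lines <- c(
    paste(c("site", colnames(x)), collapse = ","),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], sprintf("%.12g", x[i, ])), collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Default geochemical background concentrations (world-soil medians)
#'
#' The study design compares dust concentrations against soil background
#' values, but no specific background table is bundled with the measurements;
#' these defaults are representative world-soil median values (mg/kg) of the
#' kind tabulated in standard trace-element compilations (e.g.
#' Kabata-Pendias). They are a pragmatic default, not site-specific local
#' values: supply your own table via [read_background_csv()] or the
#' `[background]` config section for any serious application.
#'
#' @return named numeric vector, element -> background mg/kg.
#' @export
default_background <- function() {
  c(
    As = 6.83, Cu = 38.9, Zn = 70, Zr = 267, Sr = 175, Rb = 68,
    Pb = 27, Cr = 59.5, V = 129, Fe = 35000, Sc = 11.7
  )
}

#' Validate a background table
#'
#' @param background named numeric vector, element -> background mg/kg.
#' @return the validated named vector.
#' @export
background_table <- function(background) {
  if (is.null(names(background)) || any(names(background) == "")) {
    stopf("background table must be a named vector (element -> mg/kg)")
  }
  if (anyDuplicated(names(background))) {
    stopf("duplicate elements in background table")
  }
  background <- vapply(background, as.numeric, numeric(1L))
  bad <- names(background)[!is.finite(background) | background <= 0]
  if (length(bad) > 0L) {
    stopf("background values must be finite and > 0 (offending: %s)",
          paste(bad, collapse = ", "))
  }
  background
}

#' Read a background CSV (`element,background_mg_kg`)
#'
#' @param path path to a CSV file with columns `element` and
#'   `background_mg_kg`.
#' @return named numeric vector, element -> background mg/kg.
#' @export
read_background_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("element", "background_mg_kg") %in% names(df))) {
    stopf("background CSV must have columns 'element' and 'background_mg_kg'")
  }
  background_table(stats::setNames(df$background_mg_kg, df$element))
}

# Check every element of `conc` has a background value; return background
# aligned to conc columns.
align_background <- function(conc, background) {
  background <- background_table(background)
  missing <- setdiff(colnames(conc), names(background))
  if (length(missing) > 0L) {
    stopf("element(s) missing from background table: %s",
          paste(missing, collapse = ", "))
  }
  background[colnames(conc)]
}
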