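# Exposure taxonomy: categorical descriptors mapped to multiplier values.
#
# The multiplier grids used by the score models are decimal half-decade
# grids {..., 0.1, 0.3, 1, 3, 10, ...}; qualitative entries are expected to
# sit exactly on that grid, quantitative entries need not.

.TAXONOMY_MODELS <- c("cherrie96", "cherrie99", "stoffenmanager", "art")
.PROVENANCE_CLASSES <- c("quantitative_exact", "quantitative_category",
                         "qualitative")

.normalize_descriptor <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Load an exposure taxonomy table
#'
#' Reads a delimited taxonomy file mapping `(model, factor, descriptor)`
#' triples to dimensionless multiplier values, each tagged with a provenance
#' class (`quantitative_exact`, `quantitative_category` or `qualitative`).
#' Quantitative-category entries may additionally carry a physical range
#' (`range_low`, `range_high`, `range_units`), e.g. an application rate in
#' litres per minute.
#'
#' Descriptors are matched exactly after case-folding and whitespace
#' collapse; no fuzzy matching is performed, so a scenario author must use
#' the taxonomy's own wording.
#'
#' @param path Path to a CSV file with columns
#'   `model,factor,descriptor,value,range_low,range_high,range_units,provenance_class`.
#' @return An object of class `taxonomy_table`: a validated data frame of
#'   entries plus a `version` attribute.
#' @seealso [lookup_multiplier()], [validate_grid()]
#' @examples
#' tab <- load_taxonomy(system.file("extdata", "taxonomy_quoted.csv",
#'                                  package = "exposcore"))
#' nrow(tab)
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  required <- c("model", "factor", "descriptor", "value", "provenance_class")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("taxonomy file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in c("range_low", "range_high", "range_units")) {
    if (is.null(raw[[opt]])) raw[[opt]] <- rep(NA_character_, nrow(raw))
  }
  if (nrow(raw) == 0) {
    tab <- data.frame(model = character(), factor = character(),
                      descriptor = character(), value = numeric(),
                      range_low = numeric(), range_high = numeric(),
                      range_units = character(),
                      provenance_class = character(),
                      stringsAsFactors = FALSE)
    return(structure(tab, class = c("taxonomy_table", "data.frame"),
                     version = "0"))
  }

  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) | value <= 0)
  if (length(bad) > 0) {
    stop("taxonomy row ", bad[1], ": multiplier value must be a positive ",
         "number, got '", raw$value[bad[1]], "'")
  }
  bad_model <- which(!raw$model %in% .TAXONOMY_MODELS)
  if (length(bad_model) > 0) {
    stop("taxonomy row ", bad_model[1], ": unknown model '",
         raw$model[bad_model[1]], "'")
  }
  bad_prov <- which(!raw$provenance_class %in% .PROVENANCE_CLASSES)
  if (length(bad_prov) > 0) {
    stop("taxonomy row ", bad_prov[1], ": unknown provenance class '",
         raw$provenance_class[bad_prov[1]], "'")
  }

  tab <- data.frame(
    model = raw$model,
    factor = raw$factor,
    descriptor = .normalize_descriptor(raw$descriptor),
    value = value,
    range_low = suppressWarnings(as.numeric(raw$range_low)),
    range_high = suppressWarnings(as.numeric(raw$range_high)),
    range_units = raw$range_units,
    provenance_class = raw$provenance_class,
    stringsAsFactors = FALSE
  )
  key <- paste(tab$model, tab$factor, tab$descriptor, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate taxonomy triple: ",
         paste(strsplit(dup, "\r")[[1]], collapse = " / "))
  }
  structure(tab, class = c("taxonomy_table", "data.frame"), version = "1")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("Exposure taxonomy table: ", nrow(x), " entries",
      " (version ", attr(x, "version"), ")\n", sep = "")
  if (nrow(x) > 0) {
    counts <- table(x$model)
    cat("  models:", paste(names(counts), counts, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Look up a multiplier in a taxonomy table
#'
#' Resolves a `(model, factor, descriptor)` triple to a multiplier
#' assignment. Lookup is a pure function of its arguments: the value and
#' provenance class are returned exactly as stored.
#'
#' @param table A `taxonomy_table` from [load_taxonomy()].
#' @param model One of `"cherrie96"`, `"cherrie99"`, `"stoffenmanager"`,
#'   `"art"`.
#' @param factor Multiplier role, e.g. `"substance_emission_powder"`.
#' @param descriptor Free-text descriptor label, matched after case-folding
#'   and whitespace collapse.
#' @return A list of class `multiplier_assignment` with elements `factor`,
#'   `descriptor`, `value`, `provenance_class` and `source`
#'   (`"taxonomy lookup"`).
#' @examples
#' tab <- load_taxonomy(system.file("extdata", "taxonomy_quoted.csv",
#'                                  package = "exposcore"))
#' lookup_multiplier(tab, "cherrie96", "substance_emission_powder",
#'                   "very fine powder")$value
#' @export
lookup_multiplier <- function(table, model, factor, descriptor) {
  stopifnot(inherits(table, "taxonomy_table"))
  d <- .normalize_descriptor(descriptor)
  hit <- which(table$model == model & table$factor == factor &
               table$descriptor == d)
  if (length(hit) == 0) {
    near <- table$descriptor[table$model == model & table$factor == factor]
    msg <- paste0("no taxonomy entry for (", model, ", ", factor, ", '",
                  d, "')")
    if (length(near) > 0) {
      msg <- paste0(msg, "; known descriptors for this factor: ",
                    paste(sQuote(near), collapse = ", "))
    }
    stop(msg)
  }
  structure(list(factor = factor,
                 descriptor = table$descriptor[hit],
                 value = table$value[hit],
                 provenance_class = table$provenance_class[hit],
                 source = "taxonomy lookup"),
            class = "multiplier_assignment")
}

#' @export
print.multiplier_assignment <- function(x, ...) {
  cat(sprintf("%s ['%s'] = %g  (%s, %s)\n", x$factor, x$descriptor,
              x$value, x$provenance_class, x$source))
  invisible(x)
}

#' Test membership of the half-decade multiplier grid
#'
#' The score models draw their qualitative multipliers from the decimal
#' half-decade grid \eqn{\{10^k, 3\cdot 10^k : k \in Z\}} (..., 0.1, 0.3,
#' 1, 3, 10, ...). Membership is tested on the log10 scale with an absolute
#' tolerance of 1e-9.
#'
#' @param v Numeric vector of candidate multipliers (must be > 0 for a
#'   `TRUE` result).
#' @return Logical vector.
#' @export
on_grid <- function(v) {
  ok <- is.finite(v) & v > 0
  frac <- log10(v[ok]) %% 1
  near <- function(f, target) abs(f - target) < 1e-9
  hit <- near(frac, 0) | near(frac, 1) | near(frac, log10(3))
  out <- logical(length(v))
  out[ok] <- hit
  out
}

#' Grid step neighbours of a half-decade grid value
#'
#' For a value on the \{1,3\}x10^k grid, returns the adjacent grid values
#' one step down and one step up (e.g. 1 -> 0.3 and 3; 3 -> 1 and 10).
#'
#' @param v A single value on the grid.
#' @return Numeric vector `c(down, up)`.
#' @export
grid_neighbours <- function(v) {
  if (!on_grid(v)) stop("value ", v, " is not on the {1,3}x10^k grid")
  k <- floor(log10(v) + 1e-9)
  mant3 <- abs(log10(v) %% 1 - log10(3)) < 1e-9
  # signif() collapses binary artefacts like 3 * 10^-1 = 0.30000000000000004
  if (mant3) signif(c(10^k, 10^(k + 1)), 12)
  else signif(c(3 * 10^(k - 1), 3 * 10^k), 12)
}

#' Flag qualitative taxonomy entries off the multiplier grid
#'
#' Qualitative multipliers are expected to take values on the half-decade
#' grid; quantitative entries (exact or categorized) are exempt because they
#' encode measured or physically ranged quantities.
#'
#' @param table A `taxonomy_table`.
#' @return A data frame (class `grid_report`) with one row per flagged
#'   entry: columns `model`, `factor`, `descriptor`, `value`.
#' @export
validate_grid <- function(table) {
  stopifnot(inherits(table, "taxonomy_table"))
  qual <- table[table$provenance_class == "qualitative", , drop = FALSE]
  flagged <- qual[!on_grid(qual$value),
                  c("model", "factor", "descriptor", "value"), drop = FALSE]
  rownames(flagged) <- NULL
  class(flagged) <- c("grid_report", "data.frame")
  flagged
}

#' @export
print.grid_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("All qualitative multipliers lie on the {1,3}x10^k grid.\n")
  } else {
    cat(nrow(x), "qualitative multiplier(s) off the {1,3}x10^k grid:\n")
    print.data.frame(x)
  }
  invisible(x)
}
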