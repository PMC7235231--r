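#' Parse a chemical formula into a composition
#'
#' Turns a condensed formula such as `"SiO2"` or `"C175H102O9N4S2"` into a
#' composition object carrying the element counts, the molar mass A (g/mol,
#' from the bundled standard atomic-weight table) and the electron count Z
#' per formula unit (sum of atomic numbers).
#'
#' @param formula character scalar; element symbols each optionally followed
#'   by a positive integer count. No parentheses or charges.
#' @return An object of class `composition`: a list with `formula` (named
#'   integer vector of counts), `A` (g/mol) and `Z` (electrons per formula
#'   unit), plus the input string as `text`.
#' @export
#' @examples
#' parse_formula("SiO2")           # A ~ 60.08, Z = 30
#' parse_formula("C175H102O9N4S2") # kerogen model composition, Z = 1284
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  if (grepl("[^A-Za-z0-9]", formula))
    stop("formula contains characters other than element symbols and counts: ",
         formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, names(.atomic_weights))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(is.na(cnt)) || any(cnt <= 0))
    stop("element counts must be positive integers in: ", formula)
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(
    text    = formula,
    formula = counts,
    A       = sum(counts * .atomic_weights[names(counts)]),
    Z       = as.integer(sum(counts * .atomic_numbers[names(counts)]))
  ), class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("Composition %s: A = %.4f g/mol, Z = %d, A/Z = %.4f\n",
              x$text, x$A, x$Z, x$A / x$Z))
  invisible(x)
}

.as_composition <- function(x) {
  if (inherits(x, "composition")) x else parse_formula(x)
}

#' Molar mass per electron (A/Z)
#'
#' The A/Z ratio converts electron density to mass density: materials made of
#' light elements cluster near 2, hydrogen-rich organics fall below it
#' (model kerogen: 1.92).
#'
#' @param composition a `composition` object or a formula string.
#' @param decimals optional number of decimals to round to; `NULL` (default)
#'   returns the full-precision ratio.
#' @return numeric scalar A/Z.
#' @export
#' @examples
#' a_over_z("SiO2", decimals = 1)            # 2
#' a_over_z("Fe2O3", decimals = 1)           # 2.1
#' a_over_z("C175H102O9N4S2", decimals = 2)  # 1.92
a_over_z <- function(composition, decimals = NULL) {
  comp <- .as_composition(composition)
  r <- comp$A / comp$Z
  if (!is.null(decimals)) r <- round(r, decimals)
  r
}
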