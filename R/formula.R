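# Elemental formulas ---------------------------------------------------------
#
# Formulas are stored as named numeric vectors (element -> count). Counts may
# be fractional: the symbiosis pseudo-product is a coefficient-weighted sum of
# its component formulas. "R" is carried as a pseudo-element for generic side
# groups; it must cancel for a reaction to balance and has no defined mass.

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.990, Mg = 24.305, Cl = 35.45, K = 39.098, Ca = 40.078,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, Se = 78.971, Mo = 95.95, W = 183.84
)

#' Parse a chemical formula string
#'
#' Converts a Hill-style formula such as `"C10H12N5O13P3"` into a named
#' numeric vector of element counts. Two-letter element symbols (`Fe`, `Mg`,
#' `Mo`, ...) are supported, as are fractional counts (`"C3.5H7"`), which
#' arise in aggregate pseudo-metabolites. The symbol `R` denotes a generic
#' side group and is treated as a pseudo-element without mass.
#'
#' @param x a single formula string; `""` or `NA` yields an empty formula
#'   (flagged "unknown" by the validators).
#' @return named numeric vector of element counts (possibly empty).
#' @examples
#' parse_formula("C4H4O5")
#' parse_formula("C6H10O5")
#' @export
parse_formula <- function(x) {
  if (length(x) != 1L) stop("parse_formula() expects a single string")
  if (is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1L]]
  toks <- regmatches(x, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula: '", x, "'")
  }
  els <- sub("[0-9.]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  if (any(is.na(cnt)) || any(cnt < 0)) stop("invalid count in formula: '", x, "'")
  known <- c(names(.atomic_weights), "R")
  bad <- setdiff(els, known)
  if (length(bad)) stop("unknown element(s) in formula '", x, "': ",
                        paste(bad, collapse = ", "))
  # merge duplicate symbols
  out <- tapply(cnt, els, sum)
  out <- out[out > 0]
  stats::setNames(as.numeric(out), names(out))
}

#' Serialise an element-count vector back to a formula string
#'
#' Inverse of [parse_formula()]. Elements are emitted in Hill order (C, H,
#' then alphabetical); fractional counts are written with up to six decimal
#' places, trailing zeros trimmed.
#'
#' @param counts named numeric vector as returned by [parse_formula()].
#' @return a single string; `""` for an empty formula.
#' @export
deparse_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (!length(counts)) return("")
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  fmt1 <- function(v) {
    if (abs(v - round(v)) < 1e-9) {
      v <- round(v)
      if (v == 1) "" else format(v, scientific = FALSE)
    } else {
      sub("0+$", "", sprintf("%.6f", v))
    }
  }
  paste0(vapply(ord, function(e) paste0(e, fmt1(counts[[e]])), ""), collapse = "")
}

#' Molecular weight of a formula
#'
#' @param counts named numeric element-count vector, or a formula string.
#' @return molecular weight in g/mol (equivalently mg/mmol; divide by 1000
#'   for g/mmol, the unit used by the symbiosis composition).
#' @details Errors if the formula is empty or contains the generic group
#'   `R`, whose mass is undefined.
#' @export
molecular_weight <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (!length(counts)) stop("molecular weight of an unknown (empty) formula")
  if ("R" %in% names(counts)) {
    stop("molecular weight undefined for formulas with generic side group R")
  }
  sum(.atomic_weights[names(counts)] * counts)
}

# Sum formulas with weights: sum_i w_i * formula_i. Input: list of count
# vectors, numeric weights. Used for reaction residuals and for the
# symbiosis pseudo-product formula.
weighted_formula_sum <- function(formulas, weights) {
  stopifnot(length(formulas) == length(weights))
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(formulas)) {
    f <- formulas[[i]]
    for (e in names(f)) {
      prev <- if (is.null(acc[[e]])) 0 else acc[[e]]
      acc[[e]] <- prev + weights[i] * f[[e]]
    }
  }
  els <- ls(acc)
  out <- vapply(els, function(e) acc[[e]], 0)
  out[abs(out) > 1e-12]
}
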