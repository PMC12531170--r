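# Elemental-formula arithmetic. A formula is a named integer vector of
# element counts, class "chem_formula", stored with elements sorted by
# symbol so equality is independent of input order.

new_formula <- function(counts) {
  counts <- counts[counts != 0]
  counts <- counts[order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

#' Parse a Hill-notation elemental formula
#'
#' Accepts plain Hill notation: a sequence of element symbols, each
#' optionally followed by a positive integer count. No isotope labels,
#' charges, or parentheses.
#'
#' @param text Formula string, e.g. `"C4H8O2"`.
#' @return A `chem_formula` object (named integer vector of counts).
#' @examples
#' parse_formula("C3H6O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    data_error("empty or invalid formula string")
  # tokenize: element symbol = capital + optional lowercase; count optional
  pat <- "([A-Z][a-z]?)([0-9]*)"
  tokens <- regmatches(text, gregexpr(pat, text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    bad <- sub(paste0("^(", pat, ")*"), "", text)
    data_error(sprintf("malformed formula '%s': cannot parse at '%s'", text, bad))
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  unknown <- setdiff(syms, names(.mono_masses))
  if (length(unknown))
    data_error(sprintf("unknown element symbol(s) in '%s': %s",
                       text, paste(unique(unknown), collapse = ", ")))
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (anyNA(counts) || any(counts <= 0L))
    data_error(sprintf("malformed count in formula '%s'", text))
  new_formula(tapply(counts, syms, sum))
}

as_formula <- function(x) {
  if (inherits(x, "chem_formula")) x else parse_formula(x)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Serialize a formula back to Hill notation
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical when no carbon is present); count 1 is implicit.
#'
#' @param f A `chem_formula` or formula string.
#' @return A single string; `parse_formula(format_formula(f))` equals `f`.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return("")
  syms <- names(f)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), setdiff(sort(syms), c("C", "H")))
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(f[ord] == 1L, "", f[ord]), collapse = "")
}

#' Add or subtract elemental formulas
#'
#' Per-element arithmetic. Subtraction errors if any element count would
#' become negative (you cannot lose atoms a species does not have).
#'
#' @param f1,f2 `chem_formula` objects or formula strings.
#' @return A `chem_formula`.
#' @examples
#' formula_add("C3H6O2", "H2O")
#' formula_subtract("C6H12O6", "H2O")
#' @export
formula_add <- function(f1, f2) {
  f1 <- as_formula(f1); f2 <- as_formula(f2)
  syms <- union(names(f1), names(f2))
  counts <- vapply(syms, function(s) {
    sum(f1[s], f2[s], na.rm = TRUE)
  }, numeric(1))
  new_formula(counts)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  f1 <- as_formula(f1); f2 <- as_formula(f2)
  syms <- union(names(f1), names(f2))
  counts <- vapply(syms, function(s) {
    a <- if (s %in% names(f1)) f1[[s]] else 0L
    b <- if (s %in% names(f2)) f2[[s]] else 0L
    a - b
  }, numeric(1))
  if (any(counts < 0)) {
    neg <- names(counts)[counts < 0]
    data_error(sprintf("formula subtraction yields negative count for: %s",
                       paste(neg, collapse = ", ")))
  }
  new_formula(counts)
}

.formula_mass <- function(f, table) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(table[names(f)] * as.numeric(f))
}

#' Monoisotopic and average mass of a formula
#'
#' `monoisotopic_mass()` sums the masses of each element's lightest
#' isotope (the convention behind high-resolution small-molecule m/z);
#' `average_mass()` sums IUPAC standard atomic weights (the convention
#' behind linear-TOF protein masses). Both use the pinned tables from
#' [mass_constants()]. The empty formula has mass 0.
#'
#' @param f A `chem_formula` or Hill-notation string.
#' @return Mass in u.
#' @examples
#' monoisotopic_mass("H2O")   # ~18.0106
#' average_mass("C6H12O6")    # ~180.16
#' @export
monoisotopic_mass <- function(f) .formula_mass(f, .mono_masses)

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(f) .formula_mass(f, .avg_masses)

#' Signed mass error in parts per million
#'
#' @param measured Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `1e6 * (measured - theoretical) / theoretical`, sign preserved.
#' @examples
#' ppm_error(242.2229, 242.2227)
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) data_error("theoretical m/z must be positive")
  1e6 * (measured - theoretical) / theoretical
}
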