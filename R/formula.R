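#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic atomic masses (IUPAC 2013), Da. Precision must exceed the
# 3 ppm identification gate (1.8 mDa at m/z 600), hence 7+ decimals.
.ATOMIC_MASS <- c(
  C = 12.0000000,
  H = 1.0078250,
  D = 2.0141018,
  N = 14.0030740,
  O = 15.9949146
)

# Electron rest mass, Da. 0.9 ppm at m/z 600 -- material against a 3 ppm gate,
# so ion m/z always accounts for the gained/lost electron.
.ELECTRON_MASS <- 0.0005486

.SUPPORTED_ELEMENTS <- names(.ATOMIC_MASS)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector mapping element symbols
#' (C, H, N, O and the deuterium label D) to non-negative counts. All mass
#' and isotope computations in the package derive from these counts.
#'
#' @param ... Named integer counts, e.g. `el_formula(C = 16, H = 32, O = 2)`.
#' @return A named integer vector of class `el_formula`.
#' @examples
#' el_formula(C = 16, H = 32, O = 2) # palmitic acid
#' @export
el_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    return(structure(integer(0), class = "el_formula"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("all formula counts must be named by element symbol")
  }
  bad <- setdiff(names(counts), .SUPPORTED_ELEMENTS)
  if (length(bad) > 0) {
    abort(paste0("unknown element(s): ", paste(bad, collapse = ", ")))
  }
  if (any(counts < 0)) {
    abort("element counts must be non-negative")
  }
  counts <- counts[counts > 0]
  counts <- counts[order(match(names(counts), .SUPPORTED_ELEMENTS))]
  structure(as.integer(counts), names = names(counts), class = "el_formula")
}

#' Parse a formula string such as "C34H67NO3"
#'
#' Signed counts (e.g. `"H-2O-1"`) are accepted by [formula_add()] deltas but
#' not here: a standalone formula must have non-negative counts.
#'
#' @param x A character scalar like `"C34H67NO3"` or `""`.
#' @return An `el_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (x == "" || x == "0") return(el_formula())
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE)
  toks <- regmatches(x, m)[[1]]
  if (sum(nchar(toks)) != nchar(gsub("\\s", "", x))) {
    abort(paste0("malformed formula string: '", x, "'"))
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(n == "", "1", n)
  n <- as.integer(n)
  counts <- tapply(n, el, sum)
  do.call(el_formula, as.list(counts))
}

# Signed element delta ("H-3O-1" = minus three H, minus one O); used by
# fragment-rule templates. Returns a plain named numeric vector.
.parse_delta <- function(x) {
  x <- trimws(x %||% "")
  if (x == "" || x == "0") return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE)
  toks <- regmatches(x, m)[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  bad <- setdiff(el, .SUPPORTED_ELEMENTS)
  if (length(bad) > 0) abort(paste0("unknown element(s) in delta: ", paste(bad, collapse = ", ")))
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(n == "", "1", n)
  tapply(as.numeric(n), el, sum)
}

.as_counts <- function(f) {
  out <- stats::setNames(rep(0, length(.SUPPORTED_ELEMENTS)), .SUPPORTED_ELEMENTS)
  out[names(f)] <- as.numeric(f)
  out
}

#' Add two elemental formulas (element-wise)
#' @param a,b `el_formula` objects.
#' @return An `el_formula`.
#' @export
formula_add <- function(a, b) {
  counts <- .as_counts(a) + .as_counts(b)
  do.call(el_formula, as.list(counts[counts != 0]))
}

#' Subtract elemental formulas (element-wise; negative counts are an error)
#' @param a,b `el_formula` objects.
#' @return An `el_formula`.
#' @export
formula_subtract <- function(a, b) {
  counts <- .as_counts(a) - .as_counts(b)
  if (any(counts < 0)) {
    abort(paste0(
      "formula subtraction yields negative count for: ",
      paste(names(counts)[counts < 0], collapse = ", ")
    ))
  }
  do.call(el_formula, as.list(counts[counts != 0]))
}

#' Scale a formula by an integer multiplier
#' @param f An `el_formula`.
#' @param n Non-negative integer.
#' @return An `el_formula`.
#' @export
formula_multiply <- function(f, n) {
  stopifnot(n >= 0, n == round(n))
  counts <- .as_counts(f) * n
  do.call(el_formula, as.list(counts[counts != 0]))
}

# Apply a signed delta to a formula; errors on negative result.
.formula_shift <- function(f, delta) {
  counts <- .as_counts(f)
  counts[names(delta)] <- counts[names(delta)] + delta
  if (any(counts < 0)) {
    abort(paste0(
      "formula delta yields negative count for: ",
      paste(names(counts)[counts < 0], collapse = ", ")
    ))
  }
  do.call(el_formula, as.list(counts[counts != 0]))
}

#' @export
format.el_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' @export
print.el_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times lightest-isotope mass over all elements; deuterium D is
#' treated as its own (pure) species.
#'
#' @param f An `el_formula` or formula string.
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass(parse_formula("H2O")) # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0) return(0)
  bad <- setdiff(names(f), names(.ATOMIC_MASS))
  if (length(bad) > 0) abort(paste0("unknown element(s): ", paste(bad, collapse = ", ")))
  sum(.ATOMIC_MASS[names(f)] * as.numeric(f))
}

#' Ion m/z of a neutral species under the platform's adducts
#'
#' Ceramides are measured as acetate adducts in negative mode
#' (`[M+CH3COO]-`), the neutral classes (CE, DAG, TAG, derivatized
#' cholesterol) as ammonium adducts in positive mode (`[M+NH4]+`). The
#' electron mass is included: it amounts to 0.9 ppm at m/z 600, which matters
#' against a 3 ppm identification gate.
#'
#' @param neutral_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct `"acetate"` or `"ammonium"`.
#' @return m/z of the singly charged ion.
#' @export
adduct_mz <- function(neutral_mass, adduct = c("acetate", "ammonium")) {
  adduct <- match.arg(adduct)
  if (any(neutral_mass <= 0)) abort("neutral_mass must be positive")
  if (adduct == "acetate") {
    neutral_mass + monoisotopic_mass(el_formula(C = 2, H = 3, O = 2)) + .ELECTRON_MASS
  } else {
    neutral_mass + monoisotopic_mass(el_formula(N = 1, H = 4)) - .ELECTRON_MASS
  }
}

#' Polarity of an adduct
#' @param adduct `"acetate"` or `"ammonium"`.
#' @return `"-"` or `"+"`.
#' @export
adduct_polarity <- function(adduct) {
  ifelse(adduct == "acetate", "-", "+")
}

#' Replace hydrogens with deuterium (stable-isotope label)
#'
#' Models deuterated internal standards: each substitution raises the
#' monoisotopic mass by mass(D) - mass(H) = 1.0062768 Da.
#'
#' @param f An `el_formula`.
#' @param n_deuterium Number of H to replace (<= H count).
#' @return The labelled `el_formula`.
#' @export
apply_label <- function(f, n_deuterium) {
  stopifnot(n_deuterium >= 0, n_deuterium == round(n_deuterium))
  if (n_deuterium == 0) return(f)
  h <- .as_counts(f)[["H"]]
  if (n_deuterium > h) {
    abort(paste0("cannot label ", n_deuterium, " H in a formula with only ", h, " H"))
  }
  .formula_shift(f, c(H = -n_deuterium, D = n_deuterium))
}
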