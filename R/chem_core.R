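# Elemental-composition arithmetic and m/z bookkeeping.
#
# Masses are tabulated to six decimals, which reproduces TOF lockmass
# calibrants ([M+H]+ of carbamazepine 237.10224, reserpine 609.28066) to the
# five decimals instruments print.

#' Isotope and atomic-weight tables
#'
#' Named numeric vectors of elemental masses used throughout the package:
#' `ELEMENT_MONO` (mass of the most abundant isotope, Da), `ELEMENT_AVG`
#' (IUPAC standard atomic weights, Da) and `ELEMENT_NOMINAL` (integer nominal
#' masses). The element table is deliberately restricted to the elements that
#' occur in ribonucleosides and their hydrazine products (CHNOPS plus F for
#' the flunarizine lockmass).
#'
#' @format Named numeric vectors with one entry per supported element symbol.
#' @export
ELEMENT_MONO <- c(
  C = 12.000000, H = 1.007825, N = 14.003074,
  O = 15.994915, P = 30.973762, S = 31.972071, F = 18.998403
)

#' @rdname ELEMENT_MONO
#' @export
ELEMENT_AVG <- c(
  C = 12.011, H = 1.008, N = 14.007,
  O = 15.999, P = 30.973762, S = 32.06, F = 18.998403
)

#' @rdname ELEMENT_MONO
#' @export
ELEMENT_NOMINAL <- c(C = 12, H = 1, N = 14, O = 16, P = 31, S = 32, F = 19)

#' Cation masses for positive-mode adducts
#'
#' Masses added per charge in positive mode. The electron mass is absorbed
#' into these constants (the common m/z = (M + z * 1.007276)/z convention for
#' protons), so no separate electron correction is applied.
#'
#' @format Named numeric vector, Da per cation.
#' @export
CATION_MASS <- c(
  H = 1.007276, Na = 22.989218, K = 38.963158, NH4 = 18.033823
)

.elements <- names(ELEMENT_MONO)

#' Build an elemental composition
#'
#' An elemental composition is a named integer vector of element counts with
#' class `elem_comp`. Stored chemical species carry non-negative counts;
#' signed counts are allowed so that reaction deltas (e.g. the -C3O loss of
#' the uridine/hydrazine reaction) can be expressed in the same algebra.
#'
#' @param ... Element counts as named arguments, e.g. `C = 9, H = 12`.
#'   Alternatively a single named numeric vector.
#' @return An `elem_comp` object.
#' @examples
#' elemental_composition(C = 9, H = 12, N = 2, O = 6)
#' @export
elemental_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) counts <- numeric(0)
  bad <- setdiff(names(counts), .elements)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(.elements, collapse = ", "), ")")
  }
  full <- stats::setNames(numeric(length(.elements)), .elements)
  full[names(counts)] <- full[names(counts)] + counts
  if (any(full != round(full))) stop("element counts must be integers")
  structure(full, class = "elem_comp")
}

.as_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(elemental_composition(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an elemental composition")
}

#' Parse a molecular formula
#'
#' Parses formulas such as `"C9H12N2O6"` into an [elemental_composition()].
#' Element order on input is free; [format_formula()] writes Hill order
#' (C, H, then alphabetical).
#'
#' @param text A formula string of `Element[count]` groups.
#' @return An `elem_comp` object.
#' @examples
#' parse_formula("C9H12N2O6")   # uridine
#' parse_formula("H")           # a single hydrogen
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) stop("formula is NA")
  s <- gsub("\\s", "", text)
  if (s == "") return(elemental_composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("malformed formula: '", text, "'")
  }
  counts <- numeric(0)
  for (p in pieces) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (n == "") 1 else as.numeric(n)
    if (!el %in% .elements) stop("unknown element symbol: '", el, "'")
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + n
  }
  elemental_composition(counts)
}

#' Format a composition as a Hill-order formula
#'
#' @param x An `elem_comp` (or named count vector / formula string).
#' @return A single formula string; negative counts are written with a
#'   leading minus per element (deltas are not valid input to
#'   [parse_formula()]).
#' @export
format_formula <- function(x) {
  x <- .as_comp(x)
  ord <- c("C", "H", sort(setdiff(.elements, c("C", "H"))))
  parts <- character(0)
  for (el in ord) {
    n <- x[[el]]
    if (n == 0) next
    parts <- c(parts, paste0(if (n < 0) "-" else "", el,
                             if (abs(n) != 1) abs(n) else ""))
  }
  if (!length(parts)) "" else paste(parts, collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elemental composition> ", format_formula(x),
      "  mono ", sprintf("%.6f", mono_mass(x)), " Da\n", sep = "")
  invisible(x)
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  op <- .Generic
  if (op %in% c("+", "-")) {
    if (missing(e2)) {
      stopifnot(op == "-")
      return(structure(-unclass(e1), class = "elem_comp"))
    }
    a <- unclass(.as_comp(e1))
    b <- unclass(.as_comp(e2))
    return(structure(if (op == "+") a + b else a - b, class = "elem_comp"))
  }
  if (op == "*") {
    if (inherits(e1, "elem_comp")) { comp <- e1; k <- e2 } else { comp <- e2; k <- e1 }
    stopifnot(is.numeric(k), length(k) == 1L, k == round(k))
    return(structure(unclass(comp) * k, class = "elem_comp"))
  }
  if (op == "==") return(all(unclass(.as_comp(e1)) == unclass(.as_comp(e2))))
  stop("operation '", op, "' not defined for elemental compositions")
}

.mass_from_table <- function(x, table) {
  x <- .as_comp(x)
  sum(unclass(x) * table[names(x)])
}

#' Mass of an elemental composition
#'
#' `mono_mass()` sums most-abundant-isotope masses, `avg_mass()` standard
#' atomic weights and `nominal_mass()` integer masses. All three are linear
#' in the element counts and accept signed compositions (deltas).
#'
#' @param x An `elem_comp`, a named count vector or a formula string.
#' @return Mass in Da (a plain numeric).
#' @examples
#' mono_mass("C9H12N2O6")  # uridine, 244.069538
#' avg_mass("H2O")         # 18.015
#' @export
mono_mass <- function(x) .mass_from_table(x, ELEMENT_MONO)

#' @rdname mono_mass
#' @export
avg_mass <- function(x) .mass_from_table(x, ELEMENT_AVG)

#' @rdname mono_mass
#' @export
nominal_mass <- function(x) .mass_from_table(x, ELEMENT_NOMINAL)

.mass_by_kind <- function(x, kind = c("monoisotopic", "average", "nominal")) {
  switch(match.arg(kind),
         monoisotopic = mono_mass(x),
         average = avg_mass(x),
         nominal = nominal_mass(x))
}

#' Describe a positive-mode ion
#'
#' An ion descriptor fixes the charge state and the multiset of cation
#' adducts carrying it. By default all charges are protons; mixed profiles
#' such as three protons plus one sodium are given as named counts.
#'
#' @param z Positive integer charge state.
#' @param adducts Named integer vector of cation counts over
#'   `names(CATION_MASS)`; must sum to `z`. Default: `z` protons.
#' @return An object of class `ion_descriptor`.
#' @examples
#' ion_descriptor(4)                    # [M+4H]4+
#' ion_descriptor(4, c(H = 3, Na = 1))  # [M+3H+Na]4+
#' @export
ion_descriptor <- function(z, adducts = NULL) {
  stopifnot(is.numeric(z), length(z) == 1L, z == round(z))
  if (z < 1) stop("charge state z must be >= 1")
  if (is.null(adducts)) adducts <- c(H = z)
  bad <- setdiff(names(adducts), names(CATION_MASS))
  if (length(bad)) stop("unknown cation(s): ", paste(bad, collapse = ", "))
  if (any(adducts < 0) || sum(adducts) != z) {
    stop("adduct counts must be non-negative and sum to the charge z")
  }
  structure(list(z = as.integer(z), adducts = adducts, polarity = "positive"),
            class = "ion_descriptor")
}

#' @export
print.ion_descriptor <- function(x, ...) {
  lab <- paste(vapply(names(x$adducts), function(a) {
    n <- x$adducts[[a]]
    paste0(if (n != 1) n else "", a)
  }, character(1))[x$adducts > 0], collapse = "+")
  cat("[M+", lab, "]", x$z, "+\n", sep = "")
  invisible(x)
}

.adduct_mass <- function(ion) sum(ion$adducts * CATION_MASS[names(ion$adducts)])

#' Convert between neutral mass and m/z
#'
#' Positive-mode convention: `m/z = (M + sum of cation masses) / z`, with the
#' electron mass absorbed into the cation constants ([CATION_MASS]).
#' `mass_from_mz()` is the exact inverse.
#'
#' @param mass Neutral mass in Da.
#' @param mz Observed or theoretical m/z.
#' @param ion An [ion_descriptor()].
#' @return m/z (resp. neutral mass) as numeric.
#' @examples
#' mz_from_mass(6452.8519, ion_descriptor(4))  # 1614.2202
#' @export
mz_from_mass <- function(mass, ion) {
  stopifnot(inherits(ion, "ion_descriptor"))
  (mass + .adduct_mass(ion)) / ion$z
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, ion) {
  stopifnot(inherits(ion, "ion_descriptor"))
  if (any(mz <= 0)) stop("m/z must be positive")
  mz * ion$z - .adduct_mass(ion)
}

#' Parts-per-million mass error
#'
#' @param observed Observed m/z (or mass).
#' @param theoretical Theoretical m/z (or mass), must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}
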