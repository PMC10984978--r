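# Molecular formulas: parsing, monoisotopic mass, protonated-ion m/z, ring and
# double-bond equivalents, and homolog-series (CH2 ladder) checks.

#' Monoisotopic atomic masses
#'
#' Frozen monoisotopic masses (Da) of the most abundant isotope of each
#' supported element, plus the proton and electron masses. Values are the
#' standard reference values (AME2020 / CODATA), stored as constants so all
#' results are reproducible offline.
#'
#' @format Named numeric vector of masses in Da. The proton and electron
#'   masses are available via [proton_mass()] and [electron_mass()].
#' @export
atomic_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  Br = 78.9183371,
  F  = 18.99840322,
  I  = 126.904473,
  Si = 27.9769265325,
  Se = 79.9165213,
  Fe = 55.9349375
)

#' @rdname atomic_masses
#' @export
proton_mass <- function() 1.007276466879

#' @rdname atomic_masses
#' @export
electron_mass <- function() 0.000548579909

# Halogens are counted like hydrogen in the unsaturation formula.
.halogens <- c("F", "Cl", "Br", "I")

#' Parse a molecular formula string
#'
#' Accepts plain concatenations of element symbols each optionally followed by
#' an integer count (`"C25H27O10"`). Typographic subscript markup (underscores
#' and other non-alphanumeric characters, as found in journal tables) is
#' stripped before parsing. Repeated symbols accumulate, so `"CH3CH3"` parses
#' to `C2H6`.
#'
#' @param text Formula string.
#' @return An object of class `molecular_formula`: a named integer vector of
#'   element counts in Hill order (C first, then H, then the rest
#'   alphabetically).
#' @examples
#' parse_formula("C25H27O10")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single string")
  clean <- gsub("[^A-Za-z0-9]", "", text)
  if (!nzchar(clean)) stop("empty formula string: ", sQuote(text))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(clean))
    stop("cannot parse formula: ", sQuote(text))
  counts <- integer(0)
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    num <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(atomic_masses))
      stop("unknown element symbol ", sQuote(sym), " in formula ", sQuote(text))
    if (n < 1L)
      stop("zero or negative count for ", sQuote(sym), " in formula ", sQuote(text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  structure(counts[hill_order(names(counts))], class = "molecular_formula")
}

# Hill convention: carbon, then hydrogen, then remaining symbols alphabetically
# (purely alphabetical when no carbon is present).
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' @export
format.molecular_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular formula> ", format(x),
      "  (", format(round(monoisotopic_mass(x), 5), nsmall = 5), " Da)\n", sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' Plain sum of atom counts times monoisotopic atomic masses, with no electron
#' correction: this is the convention behind printed "calcd." values for
#' protonated-ion formulas in natural-product papers (the ion formula already
#' includes the extra hydrogen).
#'
#' @param f A `molecular_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C36H40NO15S") # 758.21187
#' monoisotopic_mass("H2O")         # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(atomic_masses[names(f)] * unclass(f))
}

#' Protonated-ion m/z of a neutral formula
#'
#' With `electron_correction = FALSE` (default) adds the mass of one hydrogen
#' atom, which bit-matches the printed "calcd." convention for `[M+H]+`
#' formulas; with `TRUE` adds the bare proton mass (physically exact for a
#' +1 cation).
#'
#' @param neutral Neutral `molecular_formula` or string; an empty string is
#'   treated as a bare proton.
#' @param electron_correction Logical; see Details.
#' @return m/z of the singly protonated ion.
#' @examples
#' protonated_mz("C25H26O10") # 487.1604 (fridamycin A)
#' @export
protonated_mz <- function(neutral, electron_correction = FALSE) {
  base <- if (is.character(neutral) && length(neutral) == 1L &&
              !nzchar(gsub("[^A-Za-z0-9]", "", neutral))) 0
          else monoisotopic_mass(neutral)
  adder <- if (electron_correction) proton_mass() else atomic_masses[["H"]]
  base + adder
}

#' Ring and double-bond equivalents (degrees of unsaturation)
#'
#' RDBE = C - H/2 + N/2 + 1. Oxygen, sulfur and phosphorus do not contribute;
#' halogens are counted like hydrogen.
#'
#' @param f A `molecular_formula` or formula string.
#' @return Integer or half-integer degrees of unsaturation.
#' @examples
#' rdbe("C36H39NO15S") # 18
#' rdbe("C25H26O10")   # 13
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(e) sum(unclass(f)[names(f) %in% e])
  cnt("C") - (cnt("H") + cnt(.halogens)) / 2 + cnt("N") / 2 + 1
}

#' Consecutive m/z spacings and CH2 homolog-series detection
#'
#' Computes consecutive differences of an ascending list of ion m/z values and
#' flags a CH2 homolog ladder (e.g. lipopeptide congeners differing in fatty
#' acid chain length) when every rounded difference is 14 and every exact
#' difference lies within `tol` of the CH2 unit mass, 14.01565 Da.
#'
#' @param mz_values Ascending numeric vector, length >= 2.
#' @param tol Absolute tolerance (Da) around the CH2 mass; default 0.03.
#' @return List with `diffs` (exact consecutive differences), `rounded`
#'   (nearest-integer roundings) and `ch2_series` (single logical).
#' @examples
#' homolog_spacing(c(1029.5404, 1043.5591, 1057.5642, 1071.5880))
#' @export
homolog_spacing <- function(mz_values, tol = 0.03) {
  if (length(mz_values) < 2L) stop("need at least two m/z values")
  if (is.unsorted(mz_values)) stop("m/z values must be sorted ascending")
  ch2 <- monoisotopic_mass("CH2")
  d <- diff(mz_values)
  list(
    diffs = d,
    rounded = round(d),
    ch2_series = all(round(d) == 14) && all(abs(d - ch2) <= tol)
  )
}
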