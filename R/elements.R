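#' Monoisotopic element masses
#'
#' Masses (Da) of the most abundant isotope of each element used in lipid
#' formulas, plus deuterium for isotope-labelled internal standards.
#' CODATA/AME-derived values, 1e-8 Da precision.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' element_masses()[["C"]]
element_masses <- function() {
  c(
    C  = 12.0,
    H  = 1.00782503207,
    D  = 2.01410177785, # deuterium (2H)
    N  = 14.0030740048,
    O  = 15.9949146196,
    P  = 30.97376163,
    Na = 22.9897692809,
    S  = 31.97207100,
    K  = 38.96370668,
    Cl = 34.96885268
  )
}

#' Proton and electron mass constants (Da)
#'
#' The proton mass is the m/z shift of an \[M+H\]+ adduct; the electron mass
#' corrects cationized/anionized adduct shifts.
#'
#' @name mass-constants
#' @export
proton_mass <- function() 1.00727646688

#' @rdname mass-constants
#' @export
electron_mass <- function() 0.00054857990907

#' Parse an elemental formula string into element counts
#'
#' Accepts Hill-style condensed formulas such as `"C34H70NO7P"`. An element
#' symbol without a number counts once. The empty string is the empty formula.
#'
#' @param formula Character scalar, e.g. `"C34H70NO7P"`.
#' @return Named integer vector of element counts (possibly empty).
#' @export
#' @examples
#' parse_chem_formula("C34H70NO7P")
parse_chem_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula, perl = TRUE))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("Malformed chemical formula: '", formula, "'", call. = FALSE)
  }
  syms <- sub("\\d+$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  out <- tapply(counts, syms, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Render element counts as a condensed formula string
#'
#' Hill order: C first, H second, remaining elements alphabetical. Zero
#' counts are dropped; negative counts are an error (an invalid composition).
#'
#' @param counts Named integer vector of element counts.
#' @return Character scalar formula.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    stop("Negative element counts in formula: ",
         paste0(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
  }
  if (length(counts) == 0L) return("")
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Add two elemental formulas
#'
#' @param a,b Formula strings or named count vectors.
#' @return Named integer vector of summed counts.
#' @export
formula_add <- function(a, b) {
  ca <- if (is.character(a)) parse_chem_formula(a) else a
  cb <- if (is.character(b)) parse_chem_formula(b) else b
  syms <- union(names(ca), names(cb))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(ca)] <- out[names(ca)] + ca
  out[names(cb)] <- out[names(cb)] + cb
  out
}

#' Neutral monoisotopic mass of an elemental formula
#'
#' Exact weighted sum of monoisotopic element masses; additive over formula
#' concatenation. Unknown element symbols are an error.
#'
#' @param formula Formula string (e.g. `"C34H70NO7P"`) or named count vector.
#' @param masses Named numeric vector of element masses; defaults to
#'   [element_masses()].
#' @return Monoisotopic mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopic_mass("C34H70NO7P") # LPC(26:0), 635.4890 Da
monoisotopic_mass <- function(formula, masses = element_masses()) {
  counts <- if (is.character(formula)) parse_chem_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown) > 0L) {
    stop("Unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(masses[names(counts)] * counts)
}
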