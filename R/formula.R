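# Elemental formulas, monoisotopic masses and adduct m/z arithmetic.

# Monoisotopic (most abundant isotope) masses in u.
# Source: NIST Atomic Weights and Isotopic Compositions / AME2020 evaluation.
.element_masses <- c(
  H  = 1.00782503207,
  B  = 11.00930536,
  C  = 12.0,
  N  = 14.00307400443,
  O  = 15.99491461957,
  F  = 18.99840316273,
  Na = 22.98976928,
  Si = 27.97692653465,
  P  = 30.97376199842,
  S  = 31.9720711744,
  Cl = 34.968852682,
  K  = 38.9637064864,
  Br = 78.9183376,
  I  = 126.9044719
)

# Proton mass in u (CODATA). "+H"/"-H" adducts are modelled as proton
# gain/loss; no separate electron-mass bookkeeping.
.proton_mass <- 1.00727646

#' Parse an elemental formula string
#'
#' Parses a Hill-notation molecular formula such as `"C8H10N4O2"` into a
#' named vector of element counts. An element symbol is one capital letter
#' optionally followed by one lowercase letter; an omitted count means 1.
#' Repeated symbols are summed.
#'
#' @param text A single formula string, e.g. `"C8H10N4O2"`.
#' @return An object of class `sst_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C8H10N4O2")   # caffeine
#' parse_formula("C8HF15O2")    # perfluorooctanoic acid
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string is invalid")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula string: '", text, "'")
  syms <- sub("[0-9]*$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  if (any(counts < 1L))
    stop("element counts must be >= 1 in '", text, "'")
  unknown <- setdiff(syms, names(.element_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  out <- vapply(split(counts, syms), sum, integer(1))
  new_sst_formula(out)
}

new_sst_formula <- function(counts) {
  if (!length(counts)) stop("empty formula is invalid")
  structure(as.integer(counts)[order(names(counts))],
            names = sort(names(counts)),
            class = "sst_formula")
}

#' @export
format.sst_formula <- function(x, ...) {
  # Hill convention: C first, then H, then remaining elements alphabetically.
  nm <- names(x)
  if ("C" %in% nm) {
    ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  } else {
    ord <- sort(nm)
  }
  paste0(ord, ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.sst_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

as_formula_counts <- function(formula) {
  if (inherits(formula, "sst_formula")) return(formula)
  if (is.character(formula)) return(parse_formula(formula))
  stop("formula must be an sst_formula or a formula string")
}

#' Monoisotopic mass of a molecule
#'
#' Sums the most-abundant-isotope masses of all atoms in the formula.
#'
#' @param formula An `sst_formula` or a formula string.
#' @return Monoisotopic mass in u.
#' @examples
#' monoisotopic_mass("C8H10N4O2")  # 194.0804
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula_counts(formula)
  sum(.element_masses[names(f)] * as.numeric(f))
}

#' Adduct specification
#'
#' Builds the charged-species description used by [adduct_mz()]. The two
#' built-in electrospray adducts are proton gain (`"+H"`, charge +1) and
#' proton loss (`"-H"`, charge -1); an en-dash label (`"–H"`) is
#' accepted as a synonym for `"-H"`.
#'
#' @param label Adduct label (`"+H"` or `"-H"`), or a custom label when
#'   `mass_delta`/`charge` are supplied.
#' @param mass_delta Signed mass offset in u added to the neutral
#'   monoisotopic mass. Defaults to +/- one proton mass for the built-ins.
#' @param charge Integer ion charge; only |charge| = 1 is supported.
#' @return A list of class `sst_adduct` with fields `label`, `mass_delta`,
#'   `charge`.
#' @export
adduct_spec <- function(label, mass_delta = NULL, charge = NULL) {
  if (inherits(label, "sst_adduct")) return(label)
  lab <- gsub("–|−", "-", as.character(label))
  if (is.null(mass_delta)) {
    if (lab == "+H") {
      mass_delta <- .proton_mass; charge <- 1L
    } else if (lab == "-H") {
      mass_delta <- -.proton_mass; charge <- -1L
    } else {
      stop("unknown adduct label '", label,
           "'; supply mass_delta and charge for custom adducts")
    }
  }
  if (is.null(charge)) stop("custom adducts need an explicit charge")
  if (charge == 0L) stop("adduct charge must be non-zero")
  if (abs(charge) != 1L) stop("only singly charged adducts are supported")
  structure(list(label = lab, mass_delta = mass_delta,
                 charge = as.integer(charge)),
            class = "sst_adduct")
}

#' Theoretical adduct m/z
#'
#' Computes the expected ion m/z of a molecule under a given adduct:
#' `(monoisotopic mass + mass_delta) / |charge|`.
#'
#' @param formula An `sst_formula` or formula string.
#' @param adduct An `sst_adduct` or adduct label (`"+H"` / `"-H"`).
#' @return Theoretical m/z in u.
#' @examples
#' adduct_mz("C8H10N4O2", "+H")   # 195.0877, caffeine [M+H]+
#' adduct_mz("C8HF15O2", "-H")    # 412.9664, PFOA [M-H]-
#' @export
adduct_mz <- function(formula, adduct) {
  ad <- adduct_spec(adduct)
  (monoisotopic_mass(formula) + ad$mass_delta) / abs(ad$charge)
}

#' Signed mass error in ppm
#'
#' `(observed - theoretical) / theoretical * 1e6`; positive when the
#' observed m/z is higher than theory. Vectorised over both arguments.
#'
#' @param observed_mz Observed m/z in u.
#' @param theoretical_mz Theoretical m/z in u; must be positive.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(!is.finite(theoretical_mz)) || any(theoretical_mz <= 0))
    stop("theoretical m/z must be positive and finite")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

# Inverse of ppm_error: m/z displaced from a target by a signed ppm offset.
shift_mz <- function(mz, ppm) mz * (1 + ppm * 1e-6)
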