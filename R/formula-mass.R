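# Monoisotopic masses of the most abundant isotope per element (NIST atomic
# mass evaluation). Covers the elements seen in natural-product formulae.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,  B  = 11.0093054,    C  = 12.0,
  N  = 14.0030740048,  O  = 15.9949146196, F  = 18.99840322,
  Na = 22.9897692809,  Mg = 23.985041700,  Al = 26.98153863,
  Si = 27.9769265325,  P  = 30.97376163,   S  = 31.97207100,
  Cl = 34.96885268,    K  = 38.96370668,   Ca = 39.96259098,
  Mn = 54.9380451,     Fe = 55.9349375,    Co = 58.9331950,
  Ni = 57.9353429,     Cu = 62.9295975,    Zn = 63.9291422,
  As = 74.9215965,     Se = 79.9165213,    Br = 78.9183371,
  Mo = 97.9054082,     I  = 126.904473,    W  = 183.9509312
)

# Mass of the electron in Da; adduct shifts are cation masses, so the proton
# shift is m(H) - m(e-) = 1.007276.
.ELECTRON_MASS <- 0.00054857990907

#' Parse a molecular formula into element counts
#'
#' Accepts plain Hill-style formulae such as `"C15H22O3"`. Parentheses,
#' isotope labels and charges are not supported: reference-database formulae
#' are flat element/count strings.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C15H22O3")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.MONOISOTOPIC))
  if (length(unknown)) {
    stop("unknown element symbol(s) in '", formula, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- stats::setNames(as.integer(tab), names(tab))
  if (any(out <= 0L)) stop("non-positive element count in '", formula, "'",
                           call. = FALSE)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#'
#' @param formula Character vector of formulae.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formulaMonoisotopicMass("H2O")       # 18.0106
#' formulaMonoisotopicMass("C15H22O3")  # 250.1569
#' @export
formulaMonoisotopicMass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parseFormula(f)
    sum(counts * .MONOISOTOPIC[names(counts)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Normalise a formula string to Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically (the
#' ordering used to compare formulae across database records).
#'
#' @param formula Character vector of formulae.
#' @return Character vector of Hill-ordered formulae.
#' @export
hillFormula <- function(formula) {
  vapply(formula, function(f) {
    counts <- parseFormula(f)
    elems <- names(counts)
    rest <- sort(setdiff(elems, c("C", "H")))
    ord <- c(intersect(c("C", "H"), elems), rest)
    paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Default positive-mode adduct panel
#'
#' The three singly charged positive species searched by default:
#' `[M+H]+`, `[M+Na]+` and the in-source water loss `[M-H2O+H]+`. Shifts are
#' cation masses, i.e. they include the electron mass (protonation adds
#' +1.007276 Da, not the neutral H mass).
#'
#' @return A data.frame with columns `name`, `mass_shift` (Da) and `charge`.
#' @examples
#' adductPanel()
#' @export
adductPanel <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M-H2O+H]+"),
    mass_shift = c(
      .MONOISOTOPIC[["H"]] - .ELECTRON_MASS,
      .MONOISOTOPIC[["Na"]] - .ELECTRON_MASS,
      -(.MONOISOTOPIC[["O"]] + 2 * .MONOISOTOPIC[["H"]]) +
        .MONOISOTOPIC[["H"]] - .ELECTRON_MASS
    ),
    charge = 1L,
    stringsAsFactors = FALSE
  )
}

#' Resolve adduct names against a panel
#'
#' @param names Character vector of adduct names, or a data.frame already in
#'   panel form (returned unchanged after validation).
#' @param panel Adduct panel to resolve against; defaults to [adductPanel()].
#'   Users may extend the panel with extra singly charged positive species.
#' @return A data.frame of adduct specifications (subset of `panel`).
#' @export
resolveAdducts <- function(names, panel = adductPanel()) {
  if (is.data.frame(names)) {
    req <- c("name", "mass_shift", "charge")
    if (!all(req %in% colnames(names))) {
      stop("adduct data.frame needs columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(names) == 0L) stop("adduct panel is empty", call. = FALSE)
    if (any(names$charge != 1L)) {
      stop("only singly charged positive adducts are supported", call. = FALSE)
    }
    return(names)
  }
  if (length(names) == 0L) stop("adduct list is empty", call. = FALSE)
  bad <- setdiff(names, panel$name)
  if (length(bad)) {
    stop("unknown adduct(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(panel$name, collapse = ", "), call. = FALSE)
  }
  panel[match(names, panel$name), , drop = FALSE]
}

#' Adduct m/z for a neutral monoisotopic mass
#'
#' @param neutralMass Numeric vector of neutral monoisotopic masses (Da).
#' @param adduct An adduct name, or a one-row data.frame from the panel.
#' @return `neutralMass + mass_shift` for the resolved adduct.
#' @examples
#' adductMz(250.1569, "[M+H]+")      # 251.1642
#' adductMz(250.1569, "[M-H2O+H]+")  # 233.1536
#' @export
adductMz <- function(neutralMass, adduct) {
  spec <- resolveAdducts(adduct)
  if (nrow(spec) != 1L) stop("'adduct' must resolve to a single species",
                             call. = FALSE)
  neutralMass + spec$mass_shift
}
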