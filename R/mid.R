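#' Mass-isotopologue distribution (MID) objects
#'
#' A MID is the vector of fractional abundances of the mass shifts
#' M+0 ... M+n of an n-carbon compound, as measured after heavy-isotope
#' incorporation. For palmitate (16 carbons) the vector has 17 entries.
#'
#' @param fractions Numeric vector of length `n_carbons + 1`, non-negative,
#'   summing to 1 (renormalized internally if the deviation is within
#'   `tolerance`).
#' @param compound_label Character name of the compound (default
#'   `"palmitate"`).
#' @param n_carbons Integer number of carbons; defaults to
#'   `length(fractions) - 1`.
#' @param tolerance Maximum allowed deviation of `sum(fractions)` from 1
#'   before an error is raised; within it the vector is renormalized exactly.
#'
#' @return An object of class `"mid"`: a list with elements
#'   `compound_label`, `n_carbons` and `fractions` (named `M+0` ... `M+n`).
#' @examples
#' mid(c(0.5, 0.25, 0.25), "toy", n_carbons = 2)
#' @export
mid <- function(fractions, compound_label = "palmitate",
                n_carbons = length(fractions) - 1L, tolerance = 1e-6) {
  fractions <- as.numeric(fractions)
  n_carbons <- as.integer(n_carbons)
  if (length(n_carbons) != 1L || is.na(n_carbons) || n_carbons < 1L)
    stop("`n_carbons` must be a single positive integer", call. = FALSE)
  if (length(fractions) != n_carbons + 1L)
    stop(sprintf("MID for %d carbons must have %d fractions, got %d",
                 n_carbons, n_carbons + 1L, length(fractions)), call. = FALSE)
  if (anyNA(fractions)) stop("MID fractions must not contain NA", call. = FALSE)
  if (any(fractions < 0))
    stop("MID fractions must be non-negative", call. = FALSE)
  s <- sum(fractions)
  if (s <= 0) stop("MID fractions must not all be zero", call. = FALSE)
  if (abs(s - 1) > tolerance)
    stop(sprintf("MID fractions must sum to 1 (got %.6g)", s), call. = FALSE)
  fractions <- fractions / s
  names(fractions) <- paste0("M+", 0:n_carbons)
  structure(
    list(compound_label = as.character(compound_label)[1],
         n_carbons = n_carbons,
         fractions = fractions),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s (%d carbons)\n", x$compound_label, x$n_carbons))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Test for MID objects
#' @param x Object to test.
#' @return `TRUE` if `x` is a `"mid"` object.
#' @export
is_mid <- function(x) inherits(x, "mid")

#' Extract the fraction vector of a MID
#' @param x A `"mid"` object.
#' @return Named numeric vector `M+0` ... `M+n`.
#' @export
mid_fractions <- function(x) {
  stopifnot(is_mid(x))
  x$fractions
}

#' Mean mass shift of a MID
#'
#' The average number of extra mass units, `sum(i * fraction[i])`; equals
#' the mean number of heavy carbons per molecule.
#'
#' @param x A `"mid"` object.
#' @return A single number in `[0, n_carbons]`.
#' @export
mean_mass_shift <- function(x) {
  stopifnot(is_mid(x))
  sum((0:x$n_carbons) * x$fractions)
}

#' Isotope specification
#'
#' Carries the natural abundance of the heavy carbon isotope used for
#' convolution and correction of MIDs. Only carbon is considered: palmitate
#' is measured as the carboxylate anion in negative mode, where H/O isotope
#' contributions are negligible at the resolving power used for fatty acids.
#'
#' @param a13C Natural 13C atom fraction; default 0.0107 (IUPAC
#'   representative value). Must satisfy `0 <= a13C < 0.5`.
#' @return An object of class `"isotope_spec"`.
#' @export
isotope_spec <- function(a13C = 0.0107) {
  a13C <- as.numeric(a13C)
  if (length(a13C) != 1L || is.na(a13C) || a13C < 0 || a13C >= 0.5)
    stop("`a13C` must be a single value in [0, 0.5)", call. = FALSE)
  structure(list(a13C = a13C), class = "isotope_spec")
}

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope_spec> a13C = %g\n", x$a13C))
  invisible(x)
}

#' Normalize raw ion intensities to a MID
#'
#' Converts a vector of non-negative isotopologue ion intensities
#' (M+0 ... M+n) to fractional abundances by dividing by the total.
#'
#' @param raw Numeric vector of ion intensities, length `n_carbons + 1`.
#' @param compound_label Compound name stored in the MID.
#' @param n_carbons Number of carbons; defaults to `length(raw) - 1`.
#' @return A `"mid"` object with `fractions = raw / sum(raw)`.
#' @examples
#' normalize_intensities(c(2, 1, 1), "toy")
#' @export
normalize_intensities <- function(raw, compound_label = "palmitate",
                                  n_carbons = length(raw) - 1L) {
  raw <- as.numeric(raw)
  n_carbons <- as.integer(n_carbons)
  if (length(raw) != n_carbons + 1L)
    stop(sprintf("expected %d intensities for %d carbons, got %d",
                 n_carbons + 1L, n_carbons, length(raw)), call. = FALSE)
  if (anyNA(raw)) stop("intensities must not contain NA", call. = FALSE)
  if (any(raw < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (sum(raw) <= 0) stop("empty signal: all intensities are zero", call. = FALSE)
  mid(raw / sum(raw), compound_label = compound_label, n_carbons = n_carbons)
}
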