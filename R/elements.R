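# Element lookup tables used by bond perception and the point-charge dipole.
# Covalent radii (Angstrom, single-bond consensus values); atomic numbers for
# the center-of-nuclear-charge origin.

.covalent_radius <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

.atomic_number <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
  Cl = 17, Ar = 18, K = 19, Ca = 20, Br = 35, I = 53
)

#' Covalent radius of an element
#'
#' @param element Character vector of element symbols (case-sensitive, e.g.
#'   `"C"`, `"Cl"`).
#' @return Numeric vector of covalent radii in Angstrom.
#' @examples
#' covalent_radius(c("C", "H"))
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

atomic_number <- function(element) {
  z <- .atomic_number[element]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}
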