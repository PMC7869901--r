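#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (Angstrom) and
#' angles (degrees).  The orthogonalization convention is the standard PDB
#' one: a along x, b in the xy plane.
#'
#' @param a,b,c cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma cell angles in degrees; must lie in (0, 180).
#' @return An object of class `unit_cell` with components `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the 3x3 orthogonalization matrix `orth`
#'   (fractional -> orthogonal Angstrom), its inverse `frac`, and the cell
#'   volume `volume` in cubic Angstrom.
#' @examples
#' uc <- unit_cell(60, 60, 60)
#' uc$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # squared volume factor; non-positive means the angles are inconsistent
  vfac2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac2 <= 0) stop("unit cell angles are geometrically inconsistent")
  vfac <- sqrt(vfac2)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * vfac / sg), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    orth = orth, frac = solve(orth), volume = a * b * c * vfac),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to orthogonal coordinates
#'
#' @param cell a [unit_cell()].
#' @param x numeric vector of length 3, or an n x 3 matrix of fractional
#'   coordinates.
#' @return Coordinates in orthogonal Angstrom, same shape as the input.
#' @export
frac_to_orth <- function(cell, x) {
  if (is.matrix(x)) t(cell$orth %*% t(x)) else as.numeric(cell$orth %*% x)
}

#' Orthogonal to fractional coordinates
#'
#' @inheritParams frac_to_orth
#' @param x coordinates in orthogonal Angstrom.
#' @export
orth_to_frac <- function(cell, x) {
  if (is.matrix(x)) t(cell$frac %*% t(x)) else as.numeric(cell$frac %*% x)
}

#' Resolution of reflections
#'
#' d-spacing (Angstrom) of Miller indices in a given cell, via the
#' reciprocal metric: the scattering vector of h is t(frac) %*% h and
#' d = 1 / |s|.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer vector of length 3 or an n x 3 matrix of Miller indices.
#' @return d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  s <- hkl %*% cell$frac          # rows are scattering vectors (A^-1)
  1 / sqrt(rowSums(s^2))
}

#' Minimum-image origin distance of a fractional vector
#'
#' Shortest orthogonal distance (Angstrom) from the origin to any lattice
#' image of a fractional position, scanning the 27 neighbouring lattice
#' translations.
#'
#' @param cell a [unit_cell()].
#' @param frac fractional coordinates (length 3, or n x 3 matrix).
#' @return distance(s) in Angstrom.
#' @export
min_image_dist <- function(cell, frac) {
  if (!is.matrix(frac)) frac <- matrix(frac, ncol = 3)
  shifts <- as.matrix(expand.grid(u = -1:1, v = -1:1, w = -1:1))
  d2 <- matrix(Inf, nrow(frac), 1)
  f <- frac - floor(frac)
  for (i in seq_len(nrow(shifts))) {
    x <- sweep(f, 2, shifts[i, ], "+") %*% t(cell$orth)
    d2 <- pmin(d2, rowSums(x^2))
  }
  sqrt(as.numeric(d2))
}
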