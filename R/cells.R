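#' Construct a unit cell
#'
#' A unit cell is described by its three edge lengths (in Angstrom) and three
#' inter-axial angles (in degrees). The constructor validates the geometry:
#' lengths must be positive, angles must lie in (0, 180) degrees, and the
#' metric tensor must be positive definite (i.e. the cell must enclose a
#' positive volume).
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Inter-axial angles in degrees. Defaults describe an
#'   orthogonal cell.
#' @return An object of class `unit_cell`: a named list with the six cell
#'   parameters plus the direct metric tensor `g` and its inverse `g_star`.
#' @examples
#' ice <- unit_cell(4.4975, 4.4975, 7.3224, 90, 90, 120)
#' d_spacing(ice, c(0, 0, 2))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("unit cell lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  g <- matrix(c(
    a * a,     a * b * cg, a * c * cb,
    a * b * cg, b * b,     b * c * ca,
    a * c * cb, b * c * ca, c * c
  ), 3, 3)
  det_g <- det(g)
  if (!is.finite(det_g) || det_g <= 0) {
    stop("degenerate unit cell: metric tensor is not positive definite",
         call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         g = g, g_star = solve(g), volume = sqrt(det_g)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the interplanar spacing d (in Angstrom) for one or more Miller
#' index triplets via the general triclinic reciprocal metric,
#' 1/d^2 = h' G* h, where G* is the inverse of the direct metric tensor.
#' The inverse resolution s = 1/d (in 1/Angstrom) is the abscissa used by all
#' the scoring machinery in this package.
#'
#' @param cell A [unit_cell()].
#' @param hkl Either a length-3 integer vector or an n x 3 matrix of Miller
#'   indices. The zero triplet (0,0,0) is rejected.
#' @return A numeric vector of d-spacings in Angstrom.
#' @seealso [inv_resolution()] for s = 1/d.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3) stop("hkl must have three columns", call. = FALSE)
  if (any(rowSums(hkl != 0) == 0)) {
    stop("the (0,0,0) triplet has no d-spacing", call. = FALSE)
  }
  inv_d2 <- rowSums((hkl %*% cell$g_star) * hkl)
  1 / sqrt(inv_d2)
}

#' Inverse resolution s = 1/d
#'
#' @inheritParams d_spacing
#' @return Numeric vector of inverse resolutions in 1/Angstrom.
#' @export
inv_resolution <- function(cell, hkl) 1 / d_spacing(cell, hkl)

#' Reference ice unit cells
#'
#' Default lattice parameters for hexagonal ice Ih (a = b = 4.4975 A,
#' c = 7.3224 A, gamma = 120 deg) and cubic ice Ic (a = 6.358 A, very close to
#' a_hex * sqrt(2)). These cells place the powder rings of the two polymorphs
#' at the positions used throughout the detection pipeline; both can be
#' overridden wherever a cell argument is accepted.
#'
#' @return A list with elements `hex` and `cubic`, each a [unit_cell()].
#' @export
ice_cells <- function() {
  list(
    hex   = unit_cell(4.4975, 4.4975, 7.3224, 90, 90, 120),
    cubic = unit_cell(6.358, 6.358, 6.358, 90, 90, 90)
  )
}
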