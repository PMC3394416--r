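#' Slant angle of barrel strands
#'
#' For a regular barrel with n strands and shear number S, the strands tilt
#' against the barrel axis by \eqn{\theta = \arctan(hS / (dn))}, where h is
#' the rise per residue along a strand and d the inter-strand distance.
#'
#' @param n Number of strands.
#' @param S Shear number.
#' @param h Rise per residue, Angstrom.
#' @param d Inter-strand distance, Angstrom.
#' @return Angle in radians, in [0, pi/2).
#' @examples
#' slant_angle(8, 10) * 180 / pi # ~43 degrees
#' @export
slant_angle <- function(n, S, h = 3.3, d = 4.4) {
  stopifnot(n > 0, S >= 0, h > 0, d > 0)
  atan(h * S / (d * n))
}

#' Shear number from relative shears
#'
#' The shear number of a closed barrel is the sum of the n relative shears
#' around the barrel (the pair of the last and first strands included); for
#' an open sheet it is the sum over the n - 1 consecutive pairs.
#'
#' @param relative_shears Integer vector of per-adjacent-pair relative
#'   shears; length n for \code{closed = TRUE}, n - 1 for an open sheet.
#' @param closed Whether the structure closes into a barrel.
#' @return The integer sum S.
#' @examples
#' shear_number(c(1, 1, 1, 2, 1, 1, 1, 2)) # 10
#' @export
shear_number <- function(relative_shears, closed = TRUE) {
  if (length(relative_shears) == 0L) stop("empty relative-shear list")
  sum(relative_shears)
}

#' Residues required to span the membrane
#'
#' A strand tilted by theta from the barrel axis advances h * cos(theta)
#' along the axis per residue, so crossing a membrane of the given
#' thickness takes ceil(thickness / (h cos theta)) residues. Tilt never
#' shortens the required span.
#'
#' @param theta Slant angle from the barrel axis, radians, in [0, pi/2).
#' @param membrane_thickness Membrane thickness, Angstrom.
#' @param h Rise per residue, Angstrom.
#' @return Integer residue count.
#' @examples
#' span_residues(0, 30, 3.3) # 10
#' @export
span_residues <- function(theta, membrane_thickness = 30, h = 3.3) {
  if (theta < 0 || theta >= pi / 2) stop("theta must lie in [0, pi/2)")
  stopifnot(membrane_thickness >= 0, h > 0)
  as.integer(ceiling(membrane_thickness / (h * cos(theta))))
}
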