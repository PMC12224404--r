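#' Laplacian phase unwrapping
#'
#' Removes 2*pi discontinuities from a wrapped 3D phase volume by solving
#' `lap(phi_u) = cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi))`
#' spectrally. The identity holds exactly in the continuum because the
#' right-hand side can be evaluated from the wrapped phase alone (sine and
#' cosine are wrap-invariant). Both the forward Laplacians and the inverse are
#' applied on an even-symmetric mirror extension of the grid, so boundaries
#' behave as Neumann rather than periodic; the returned solution has zero mean
#' over the grid (the Laplacian's nullspace is fixed that way).
#'
#' @param wrapped 3D array of wrapped phase in (-pi, pi].
#' @return 3D array of unwrapped phase, zero mean over the full grid.
#' @examples
#' phi <- array(0, c(8, 8, 8))
#' stopifnot(all(unwrap_laplacian(phi) == 0))
#' @export
unwrap_laplacian <- function(wrapped) {
  if (!is.array(wrapped) || length(dim(wrapped)) != 3L)
    stop("`wrapped` must be a 3D array")
  if (any(dim(wrapped) < 3L))
    stop("degenerate grid: every dimension must have at least 3 voxels")
  if (!all(is.finite(wrapped))) stop("phase values must be finite")
  if (any(wrapped <= -pi - 1e-9) || any(wrapped > pi + 1e-9))
    stop("`wrapped` must lie in (-pi, pi]; use wrap_phase() first")

  eig <- .lap_eigenvalues(dim(wrapped))
  s <- sin(wrapped)
  cs <- cos(wrapped)
  rhs <- cs * .laplacian_apply(s, eig) - s * .laplacian_apply(cs, eig)
  out <- .laplacian_solve(rhs, eig)
  out - mean(out)
}
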