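# Mollweide projection: equal-area pseudocylindrical map of viewing
# directions, used to display receptive fields on the visual field.

#' Mollweide projection of unit viewing directions
#'
#' Projects unit vectors to 2-D map coordinates. Latitude `phi = asin(z)`
#' (equator at elevation 0) and longitude `lambda = atan2(y, x)` (frontal
#' midline at longitude 0) follow the eyemap convention with +x frontal and
#' +z dorsal. The auxiliary angle theta solves
#' `2*theta + sin(2*theta) = pi * sin(phi)` by Newton iteration; then
#' `x = (2*sqrt(2)/pi) * R * lambda * cos(theta)` and
#' `y = sqrt(2) * R * sin(theta)`. The poles are handled analytically
#' (theta = +/- pi/2).
#'
#' @param directions numeric matrix (n x 3) of unit vectors (checked to
#'   1e-6).
#' @param R map radius scale (default 1).
#' @param tol Newton convergence tolerance on theta (default 1e-12).
#' @return numeric matrix (n x 2) of map coordinates, columns `x`, `y`.
#' @examples
#' mollweide_project(rbind(c(1, 0, 0), c(0, 0, 1)))
#' @export
mollweide_project <- function(directions, R = 1, tol = 1e-12) {
  directions <- as.matrix(directions)
  if (is.null(dim(directions)) || ncol(directions) != 3) {
    stop("directions must be an n x 3 matrix")
  }
  stopifnot(R > 0, tol > 0)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  phi <- asin(pmin(1, pmax(-1, directions[, 3])))
  lambda <- atan2(directions[, 2], directions[, 1])
  theta <- mollweide_theta(phi, tol)
  cbind(
    x = (2 * sqrt(2) / pi) * R * lambda * cos(theta),
    y = sqrt(2) * R * sin(theta)
  )
}

# Newton solve of 2*theta + sin(2*theta) = pi*sin(phi), vectorized.
mollweide_theta <- function(phi, tol) {
  theta <- phi
  target <- pi * sin(phi)
  at_pole <- abs(abs(phi) - pi / 2) < 1e-12
  theta[at_pole] <- sign(phi[at_pole]) * pi / 2
  active <- !at_pole
  for (iter in 1:50) {
    if (!any(active)) break
    f <- 2 * theta[active] + sin(2 * theta[active]) - target[active]
    fp <- 2 + 2 * cos(2 * theta[active])
    fp[fp < 1e-12] <- 1e-12   # derivative vanishes only at the poles
    step <- f / fp
    theta[active] <- theta[active] - step
    done <- abs(step) < tol
    active[active] <- !done
  }
  theta
}
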