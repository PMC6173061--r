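#' Degree/radian conversion
#'
#' Angles are stored in radians everywhere inside the package; degrees appear
#' only at I/O boundaries (files, CLI, printed output).
#'
#' @param deg,rad angle(s) in degrees / radians.
#' @return the converted angle(s).
#' @export
degToRad <- function(deg) deg * pi / 180

#' @rdname degToRad
#' @export
radToDeg <- function(rad) rad * 180 / pi

#' Convert a fiber orientation to its unit-vector form
#'
#' The convention is \eqn{v = (\cos\alpha \cos\varphi, \cos\alpha \sin\varphi,
#' \sin\alpha)}: \eqn{\alpha} is the elevation out of the sectioning (x-y)
#' plane, \eqn{\varphi} the azimuth within it.
#'
#' @param phi,alpha direction and inclination angles in radians (vectorized).
#' @return an `n x 3` matrix of unit vectors (a plain length-3 vector if
#'   `n = 1`).
#' @examples
#' orientationToVector(0, 0)            # in-plane fiber along x
#' orientationToVector(pi / 4, pi / 3)
#' @export
orientationToVector <- function(phi, alpha) {
  ca <- cos(alpha)
  v <- cbind(x = ca * cos(phi), y = ca * sin(phi), z = sin(alpha))
  if (nrow(v) == 1L) drop(v) else v
}

#' Convert a vector to the half-sphere fiber orientation
#'
#' Fiber orientations are axes, not directions: \eqn{v} and \eqn{-v} denote
#' the same fiber. The returned representative lies in the standard 3D-PLI
#' parameter space \eqn{\varphi \in [0, \pi)},
#' \eqn{\alpha \in [-\pi/2, \pi/2]}. Vectors within `1e-9` of the poles
#' \eqn{\pm z}, where the azimuth is degenerate, map deterministically to
#' \eqn{(\varphi = 0, \alpha = \pm\pi/2)}.
#'
#' @param v numeric length-3 vector or `n x 3` matrix; need not be normalized
#'   but must be non-zero.
#' @return a list with components `phi` and `alpha` (radians, vectorized).
#' @examples
#' vectorToOrientation(c(0, 0, 1))
#' vectorToOrientation(c(-1, 0, 0))   # antipode of the x axis: phi = 0
#' @export
vectorToOrientation <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-300)) stop("cannot orient a zero vector")
  v <- v / nrm
  pole <- sqrt(v[, 1]^2 + v[, 2]^2) < 1e-9
  phi <- atan2(v[, 2], v[, 1])
  alpha <- asin(pmin(1, pmax(-1, v[, 3])))
  flip <- phi < 0 | phi >= pi - 1e-15
  phi[flip] <- phi[flip] %% pi
  phi[flip & phi >= pi - 1e-15] <- 0
  alpha[flip] <- -alpha[flip]
  phi[pole] <- 0
  alpha[pole] <- sign(v[pole, 3]) * pi / 2
  list(phi = phi, alpha = alpha)
}

#' Rotation matrix of the tilting stage
#'
#' Tilting the stage towards direction \eqn{\psi} by angle \eqn{\tau}
#' rotates a fiber vector by \eqn{R(\psi, \tau) = R_z(\psi) R_y(\tau)
#' R_z(-\psi)}: rotate the tilting direction onto the x axis, tilt about y,
#' rotate back.
#'
#' @param psi tilting direction angle, radians.
#' @param tau tilting angle, radians.
#' @return an orthogonal `3 x 3` matrix with determinant 1.
#' @examples
#' tiltRotationMatrix(0, degToRad(5.51))
#' @export
tiltRotationMatrix <- function(psi, tau) {
  cp <- cos(psi); sp <- sin(psi)
  ct <- cos(tau); st <- sin(tau)
  Rz <- matrix(c(cp, sp, 0, -sp, cp, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3, 3)
  Rzi <- matrix(c(cp, -sp, 0, sp, cp, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rzi
}

#' Snell-corrected in-tissue tilting angle
#'
#' Refraction at the tissue surface reduces the effective tilting angle of
#' the light path inside the section:
#' \eqn{\tau_{int} = \arcsin(\sin\tau_{stage} / n)}. For the standard 8
#' degree stage tilt and tissue refractive index 1.45 this gives 5.51
#' degrees.
#'
#' @param tauStage stage tilting angle, radians, `|tauStage| < pi/2`.
#' @param nTissue tissue refractive index, `>= 1`.
#' @return the in-tissue tilting angle in radians.
#' @examples
#' radToDeg(snellInternalAngle(degToRad(8), 1.45))  # 5.51
#' @export
snellInternalAngle <- function(tauStage, nTissue) {
  stopifnot(all(nTissue >= 1), all(abs(tauStage) < pi / 2))
  asin(sin(tauStage) / nTissue)
}

#' Apply a stage tilt to a fiber orientation
#'
#' Rotates the orientation's unit vector by [tiltRotationMatrix()] and maps
#' the result back to the half-sphere parameter space.
#'
#' @param phi,alpha fiber orientation, radians.
#' @param psi,tau tilting direction and angle, radians.
#' @return a list with components `phi` and `alpha` of the tilted
#'   orientation.
#' @examples
#' tiltOrientation(degToRad(45), degToRad(30), 0, degToRad(5.51))
#' @export
tiltOrientation <- function(phi, alpha, psi, tau) {
  v <- orientationToVector(phi, alpha)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  vectorToOrientation(v %*% t(tiltRotationMatrix(psi, tau)))
}

#' Map unbounded fit parameters into the 3D-PLI parameter space
#'
#' The ROFL optimizer works on unbounded parameters
#' \eqn{(\varphi_u, \alpha_u, d)}. The spherical symmetries
#' \deqn{\varphi = \varphi_u \bmod \pi}
#' \deqn{\alpha = ((\alpha_u + \pi/2) \bmod \pi - \pi/2) \cdot
#'   \mathrm{sgn}(1/2 - \lfloor (\varphi_u/\pi) \bmod 2 \rfloor)}
#' together with \eqn{d \mapsto |d|} (the model is odd in \eqn{d}) fold any
#' point back into \eqn{\varphi \in [0, \pi)},
#' \eqn{\alpha \in [-\pi/2, \pi/2]}, \eqn{d \ge 0} without changing the
#' model value. The map is idempotent.
#'
#' @param phiU,alphaU unbounded azimuth and inclination, radians
#'   (vectorized).
#' @param d relative thickness, may be negative; `NULL` to fold only the
#'   orientation.
#' @return a list with components `phi`, `alpha` and (if supplied) `d`.
#' @examples
#' symmetrizeOrientation(0.3, 0.2, 0.5)           # already in range
#' symmetrizeOrientation(0.3 + pi, 0.2)           # antipode: alpha flips
#' @export
symmetrizeOrientation <- function(phiU, alphaU, d = NULL) {
  s <- sign(0.5 - floor((phiU / pi) %% 2))
  out <- list(phi = phiU %% pi,
              alpha = ((alphaU + pi / 2) %% pi - pi / 2) * s)
  if (!is.null(d)) out$d <- abs(d)
  out
}

#' Acute angle between two fiber axes
#'
#' The orientation error metric: \eqn{\gamma = \arccos(|v_1 \cdot v_2|)}.
#' Because fiber orientations live on a half-sphere the angle is at most 90
#' degrees; the absolute value makes it invariant under sign flips of either
#' vector. The dot product is clamped to \eqn{[-1, 1]} before the arccos.
#'
#' @param v1,v2 unit 3-vectors (or `n x 3` matrices, compared row-wise).
#' @return angle(s) in radians, in \eqn{[0, \pi/2]}.
#' @examples
#' radToDeg(acuteAngle(c(1, 0, 0), c(0, 1, 0)))  # 90
#' acuteAngle(c(1, 0, 0), c(-1, 0, 0))           # 0: same axis
#' @export
acuteAngle <- function(v1, v2) {
  if (is.null(dim(v1))) v1 <- matrix(v1, ncol = 3)
  if (is.null(dim(v2))) v2 <- matrix(v2, ncol = 3)
  dt <- rowSums(v1 * v2)
  acos(pmin(1, abs(dt)))
}
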