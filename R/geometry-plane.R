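#' Fit the least-squares plane of a closed annular curve and project onto it
#'
#' The plane minimizes the sum of squared orthogonal distances of the curve
#' samples and passes through their centroid (total least squares via SVD).
#' Samples are then orthogonally projected and expressed in an in-plane
#' orthonormal basis, yielding the 2D curve used for area and principal-axis
#' calculations.
#'
#' The normal sign is arbitrary for a plane; to keep the saddle orientation
#' stable across frames it is chosen to have positive dot product with
#' `ref_normal` (by default the +z axis, i.e. the first frame of a recording;
#' subsequent frames should pass the previous frame's normal).
#'
#' @param spline An `annulus_spline`, or a numeric matrix of 3D curve samples.
#' @param ref_normal Reference direction for orienting the normal.
#' @return A list with `plane` (class `fitted_plane`: `centroid`, `normal`,
#'   `basis` 3x2), `xy` (samples in plane coordinates, centred on the
#'   centroid) and `residuals` (signed out-of-plane distances, mm).
#' @export
fit_plane_and_project <- function(spline, ref_normal = c(0, 0, 1)) {
  pts <- if (inherits(spline, "annulus_spline")) spline$samples else as.matrix(spline)
  if (nrow(pts) < 3L) stop("need at least 3 samples to fit a plane")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("curve samples are collinear: least-squares plane is not unique")
  }
  normal <- sv$v[, 3]
  if (sum(normal * ref_normal) < 0) normal <- -normal
  e1 <- sv$v[, 1]
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],   # normal x e1 keeps a
          normal[3] * e1[1] - normal[1] * e1[3],   # right-handed (e1,e2,normal)
          normal[1] * e1[2] - normal[2] * e1[1])
  basis <- cbind(e1, e2, deparse.level = 0)
  plane <- structure(list(centroid = ctr, normal = normal, basis = basis),
                     class = "fitted_plane")
  list(plane = plane, xy = X %*% basis, residuals = drop(X %*% normal))
}

#' Area enclosed by a closed planar curve (shoelace formula)
#'
#' Computes the area of the densely sampled projected annulus as the absolute
#' signed area of the closed sample polygon. A self-intersecting projection
#' (total turning angle not equal to one full turn) is flagged with a warning
#' and the magnitude of the signed area is still returned.
#'
#' @param xy Two-column matrix of ordered closed-curve samples (the last
#'   vertex connects back to the first).
#' @return Area with attribute `self_intersecting` (logical).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' spline_area(cbind(16 * cos(th), 11.2 * sin(th))) # ~ pi * 16 * 11.2
#' @export
spline_area <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) stop("`xy` must be an M x 2 matrix, M >= 3")
  nxt <- c(2:nrow(xy), 1L)
  a <- 0.5 * abs(sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]))

  # total turning angle: +/- 2*pi for a simple closed curve, ~0 for a figure-8
  e <- xy[nxt, , drop = FALSE] - xy
  keep <- rowSums(e^2) > 1e-24
  selfx <- FALSE
  if (a > 0 && sum(keep) >= 3) {
    ang <- atan2(e[keep, 2], e[keep, 1])
    turn <- diff(c(ang, ang[1]))
    turn <- (turn + pi) %% (2 * pi) - pi
    if (abs(sum(turn)) < pi) {
      selfx <- TRUE
      warning("projected annulus appears self-intersecting; ",
              "returning magnitude of signed area")
    }
  }
  structure(a, self_intersecting = selfx)
}

#' Principal axes of the projected annular curve
#'
#' Eigen-decomposition of the covariance of the projected 2D samples. The
#' first axis (largest variance) is designated intercommissural, the second
#' septolateral. Axis signs follow a deterministic convention (first
#' component of axis 1 non-negative; axis 2 completes a right-handed pair).
#' When the two eigenvalues are equal to within `tie_tol` (relative), the
#' curve is rotationally degenerate (near-circular): `prev_axes`, if given,
#' is reused for temporal continuity, otherwise the coordinate axes are
#' returned, and the degeneracy flag is set.
#'
#' @param xy Two-column matrix of centred projected samples.
#' @param prev_axes Optional 2x2 matrix (columns = previous frame's axes).
#' @param tie_tol Relative eigenvalue gap below which the axes are
#'   considered degenerate.
#' @return List with `axes` (2x2 matrix, columns axis1/axis2), `eigenvalues`,
#'   and `degenerate` flag.
#' @export
principal_axes <- function(xy, prev_axes = NULL, tie_tol = 1e-6) {
  xy <- as.matrix(xy)
  xy <- sweep(xy, 2, colMeans(xy))
  C <- crossprod(xy) / nrow(xy)
  if (max(abs(C)) < 1e-24) stop("curve has no planar extent")
  eg <- eigen(C, symmetric = TRUE)
  degenerate <- (eg$values[1] - eg$values[2]) < tie_tol * eg$values[1]
  if (degenerate) {
    axes <- if (!is.null(prev_axes)) prev_axes else diag(2)
    warning("near-isotropic projection: principal axes are degenerate")
  } else {
    a1 <- eg$vectors[, 1]
    s <- if (abs(a1[1]) > 1e-12) sign(a1[1]) else sign(a1[2])
    a1 <- a1 * s
    axes <- cbind(a1, c(-a1[2], a1[1]), deparse.level = 0)
  }
  list(axes = axes, eigenvalues = eg$values, degenerate = degenerate)
}

#' Intersections of a principal axis with the annular curve
#'
#' Finds the two points where the line through the in-plane centroid along
#' `axis` crosses the projected curve, and returns the corresponding 3D
#' annular points (linear interpolation between the bracketing spline
#' samples, in 3D as well as in the plane).
#'
#' @param samples3d M x 3 matrix of spline samples.
#' @param xy M x 2 matrix of their centred in-plane coordinates.
#' @param axis Unit 2-vector in plane coordinates.
#' @return List with `points` (2 x 3 matrix; first row on the positive side
#'   of the axis) and `xy` (2 x 2 matrix of in-plane crossing coordinates).
#' @export
axis_intersections <- function(samples3d, xy, axis) {
  samples3d <- as.matrix(samples3d); xy <- as.matrix(xy)
  stopifnot(nrow(samples3d) == nrow(xy))
  perp <- c(-axis[2], axis[1])
  s <- drop(xy %*% perp)
  n <- length(s)
  nxt <- c(2:n, 1L)
  cross_at <- which(s * s[nxt] < 0 | (s == 0 & s[nxt] != 0))
  if (length(cross_at) != 2L) {
    stop("axis line crosses the projected curve ", length(cross_at),
         " times (expected 2): folded or degenerate projection")
  }
  pts <- matrix(NA_real_, 2, 3)
  pxy <- matrix(NA_real_, 2, 2)
  u <- numeric(2)
  for (k in seq_along(cross_at)) {
    i <- cross_at[k]; j <- nxt[i]
    alpha <- s[i] / (s[i] - s[j])
    pts[k, ] <- (1 - alpha) * samples3d[i, ] + alpha * samples3d[j, ]
    pxy[k, ] <- (1 - alpha) * xy[i, ] + alpha * xy[j, ]
    u[k] <- sum(pxy[k, ] * axis)
  }
  if (prod(sign(u)) >= 0) {
    stop("both axis crossings lie on the same side of the centroid")
  }
  ord <- order(u, decreasing = TRUE)
  list(points = pts[ord, , drop = FALSE], xy = pxy[ord, , drop = FALSE])
}

#' Annular diameters and circularity index
#'
#' The intercommissural width (ICW) is the 3D Euclidean distance between the
#' two annular points intersected by the first principal axis; the
#' septolateral diameter (SL) the distance between the anterior and posterior
#' horn identified by the second axis. ACI = SL / ICW (1 = circular).
#'
#' @param samples3d,xy Spline samples and their in-plane coordinates, as for
#'   [axis_intersections()].
#' @param axes 2x2 matrix from [principal_axes()].
#' @return List with `icw`, `sl`, `aci`, and `horns` / `commissures`
#'   (2 x 3 matrices of the identified annular points).
#' @export
compute_dimensions_and_aci <- function(samples3d, xy, axes) {
  comm <- axis_intersections(samples3d, xy, axes[, 1])
  horn <- axis_intersections(samples3d, xy, axes[, 2])
  icw <- sqrt(sum((comm$points[1, ] - comm$points[2, ])^2))
  sl <- sqrt(sum((horn$points[1, ] - horn$points[2, ])^2))
  list(icw = icw, sl = sl, aci = sl / icw,
       horns = horn$points, commissures = comm$points)
}

#' Juncture of the septolateral and intercommissural axes
#'
#' The two annular diameters (anterior-to-posterior horn, and
#' commissure-to-commissure) intersect exactly when the annulus is planar;
#' on a saddle they are skew lines, and the juncture is taken as the
#' midpoint of their common perpendicular (the point mutually closest to
#' both diameters). This reduces to the chord intersection in the planar
#' limit and is invariant under rigid motion.
#'
#' @param sl_pts 2 x 3 matrix: the two horn points (septolateral axis).
#' @param icw_pts 2 x 3 matrix: the two commissure points.
#' @return 3D point (mm).
#' @export
axis_juncture <- function(sl_pts, icw_pts) {
  p1 <- sl_pts[1, ]; u <- sl_pts[2, ] - sl_pts[1, ]
  p2 <- icw_pts[1, ]; v <- icw_pts[2, ] - icw_pts[1, ]
  w <- p1 - p2
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * c - b^2
  if (den < 1e-12 * a * c) stop("annular diameters are parallel")
  s <- (b * e - c * d) / den
  t <- (a * e - b * d) / den
  ((p1 + s * u) + (p2 + t * v)) / 2
}

#' Non-planarity angle of the annular saddle
#'
#' Angle (degrees) subtended at the axis juncture by the anterior and
#' posterior annular horns: 180 degrees for a flat annulus, smaller as the
#' saddle deepens. The juncture is where the septolateral and
#' intercommissural axes meet (see [axis_juncture()]).
#'
#' @param ah,ph 3D positions of the anterior and posterior horns (mm).
#' @param juncture 3D position of the axis juncture (mm).
#' @return NPA in degrees, in (0, 180].
#' @examples
#' compute_npa(c(0, 11.2, 2), c(0, -11.2, 2), c(0, 0, 0)) # ~159.75
#' @export
compute_npa <- function(ah, ph, juncture) {
  v1 <- ah - juncture
  v2 <- ph - juncture
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("horn coincides with the axis juncture")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}
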