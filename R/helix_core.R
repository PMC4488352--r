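# Pure geometry of general helical curves: construction, analytic seed
# parameters from a quadruple, the turn-angle closed form, point generation,
# closest-point queries and SVD (Kabsch) superposition.

#' Construct a general helical curve
#'
#' A helical curve is parameterised by three intrinsic parameters and a rigid
#' placement. A point at phase \eqn{\tau} (radians about the axis) is
#' \deqn{x(\tau) = r_0 + R \, (r \sin\tau,\; r \cos\tau,\; (p/t)\,\tau)}
#' where \code{r} is the radius (\enc{Å}{A}), \code{p} the rise per residue
#' along the axis (\enc{Å}{A}/residue), and \code{t} the signed turn angle per
#' residue (radians; positive = right-handed). The axis direction is
#' \code{R \%*\% c(0, 0, 1)} and the curve's center (the axis point of the
#' curve frame origin) is \code{r0}.
#'
#' @param r radius in \enc{Å}{A}; must be > 0.
#' @param p rise per residue in \enc{Å}{A} (signed).
#' @param t turn angle per residue in radians; \code{0 < |t| <= pi}.
#' @param rotation 3x3 proper orthogonal placement matrix.
#' @param origin length-3 placement origin (\enc{Å}{A}).
#' @return An object of class \code{"helical_curve"}.
#' @examples
#' hc <- helical_curve(2.3, 1.5, 100 * pi / 180)
#' helix_points(hc, c(0, pi / 2))
#' @export
helical_curve <- function(r, p, t, rotation = diag(3), origin = c(0, 0, 0)) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(t), length(t) == 1L, is.finite(t))
  if (abs(t) <= 0 || abs(t) > pi + 1e-12)
    stop("turn angle t must satisfy 0 < |t| <= pi", call. = FALSE)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper orthogonal (R'R = I, det = +1)",
         call. = FALSE)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(r = r, p = p, t = t, rotation = rotation, origin = origin),
            class = "helical_curve")
}

#' @export
print.helical_curve <- function(x, ...) {
  cat(sprintf(
    "Helical curve: r = %.4f A, rise = %.4f A/residue, t = %.4f rad (%.2f deg, %s-handed)\n",
    x$r, x$p, x$t, x$t * 180 / pi, if (x$t >= 0) "right" else "left"))
  ax <- helix_axis(x)
  cat(sprintf("  axis  n  = (%.4f, %.4f, %.4f)\n", ax[1], ax[2], ax[3]))
  cat(sprintf("  center c0 = (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Axis direction of a helical curve
#'
#' @param curve a \code{\link{helical_curve}}.
#' @return Unit 3-vector \code{rotation \%*\% c(0, 0, 1)}.
#' @export
helix_axis <- function(curve) {
  stopifnot(inherits(curve, "helical_curve"))
  as.numeric(curve$rotation %*% c(0, 0, 1))
}

#' Evaluate a helical curve at given phases
#'
#' @param curve a \code{\link{helical_curve}}.
#' @param phases numeric vector of phases (radians along the curve parameter).
#' @return A \code{length(phases) x 3} matrix of points (\enc{Å}{A}).
#' @export
helix_points <- function(curve, phases) {
  stopifnot(inherits(curve, "helical_curve"), is.numeric(phases),
            all(is.finite(phases)))
  .cpp_helix_points(curve$r, curve$p, curve$t, curve$rotation, curve$origin,
                    as.numeric(phases))
}

#' Analytic seed helix parameters from a quadruple of guide atoms
#'
#' Computes (r, p, t) directly from the virtual-bond geometry of four
#' consecutive guide atoms. With bond vectors \eqn{v_1, v_2, v_3} and
#' direction-change vectors \eqn{\Delta_1 = v_1 - v_2},
#' \eqn{\Delta_2 = v_2 - v_3}:
#' \itemize{
#'   \item \eqn{\cos|t| = \Delta_1\cdot\Delta_2 / (|\Delta_1||\Delta_2|)};
#'     the sign of \code{t} is the sign of the virtual dihedral angle.
#'   \item axis estimate \eqn{\hat n = \pm \Delta_1\times\Delta_2 /
#'     |\Delta_1\times\Delta_2|}, oriented so \eqn{\hat n\cdot v_2 > 0};
#'   \item \eqn{p = v_2\cdot\hat n};
#'   \item \eqn{r = \mathrm{mean}(|\Delta_1|, |\Delta_2|) / (4\sin^2(t/2))}.
#' }
#' Exact on points generated by an ideal helix, and rigid-motion invariant.
#'
#' @param quadruple a 4x3 matrix of positions (\enc{Å}{A}), chain order.
#' @return list with components \code{r}, \code{p}, \code{t} (radians,
#'   signed), and \code{axis} (unit 3-vector estimate).
#' @export
seed_params <- function(quadruple) {
  quadruple <- as.matrix(quadruple)
  stopifnot(nrow(quadruple) == 4L, ncol(quadruple) == 3L,
            all(is.finite(quadruple)))
  v1 <- quadruple[2, ] - quadruple[1, ]
  v2 <- quadruple[3, ] - quadruple[2, ]
  v3 <- quadruple[4, ] - quadruple[3, ]
  if (min(sqrt(sum(v1^2)), sqrt(sum(v2^2)), sqrt(sum(v3^2))) < 1e-9)
    stop("degenerate quadruple: coincident consecutive points", call. = FALSE)
  d1 <- v1 - v2
  d2 <- v2 - v3
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (n1 < 1e-9 || n2 < 1e-9 || sqrt(sum(cr^2)) < 1e-9 * n1 * n2)
    stop("degenerate quadruple: collinear or non-turning points",
         call. = FALSE)
  ct <- sum(d1 * d2) / (n1 * n2)
  t_abs <- acos(max(-1, min(1, ct)))
  if (t_abs < 0.05)
    stop("degenerate quadruple: turn angle below the angular floor",
         call. = FALSE)
  axis <- cr / sqrt(sum(cr^2))
  if (sum(axis * v2) < 0) axis <- -axis
  p <- sum(v2 * axis)
  r <- mean(c(n1, n2)) / (4 * sin(t_abs / 2)^2)
  t_sign <- sign(virtual_dihedral(quadruple))
  if (t_sign == 0) t_sign <- 1
  list(r = r, p = p, t = t_sign * t_abs, axis = axis)
}

# Signed virtual dihedral of 4 points about the middle bond (radians).
virtual_dihedral <- function(quadruple) {
  b1 <- quadruple[2, ] - quadruple[1, ]
  b2 <- quadruple[3, ] - quadruple[2, ]
  b3 <- quadruple[4, ] - quadruple[3, ]
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2)
  n2 <- cx(b2, b3)
  m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Turn angle from inter-atom distance, radius and rise
#'
#' The chord between consecutive residues of a helix with radius \code{r},
#' rise \code{p} and turn angle \code{t} has length
#' \eqn{d^2 = p^2 + 4 r^2 \sin^2(t/2)}; inverting gives
#' \deqn{t = 2 \arcsin\left(\tfrac{1}{2}\sqrt{d^2 - p^2}\,/\,r\right).}
#'
#' @param d consecutive guide-atom distance (\enc{Å}{A}), > 0.
#' @param r radius (\enc{Å}{A}), > 0.
#' @param p rise per residue (\enc{Å}{A}).
#' @return Turn angle in \code{(0, pi]} (radians).
#' @export
turn_angle <- function(d, r, p) {
  stopifnot(is.numeric(d), is.numeric(r), is.numeric(p), d > 0, r > 0)
  if (d^2 < p^2)
    stop("infeasible pitch: d^2 < p^2", call. = FALSE)
  s <- sqrt(d^2 - p^2) / (2 * r)
  if (s > 1)
    stop("infeasible radius: arcsin argument exceeds 1", call. = FALSE)
  2 * asin(s)
}

#' Kabsch superposition of two corresponded point sets
#'
#' Finds the proper rotation \code{Q} (det = +1, reflection-corrected) and
#' translation \code{s} minimising the corresponded RMSD between
#' \code{Q \%*\% moving[i, ] + s} and \code{fixed[i, ]}, via SVD of the
#' cross-covariance.
#'
#' @param moving,fixed N x 3 matrices (N >= 3), corresponded by row.
#' @return list with \code{rotation} (3x3), \code{translation} (3-vector),
#'   \code{rmsd}, and \code{degenerate} (TRUE when the covariance is
#'   rank-deficient with an ambiguous minimiser; a valid minimiser is still
#'   returned deterministically).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(nrow(moving) >= 3L, ncol(moving) == 3L,
            all(dim(moving) == dim(fixed)),
            all(is.finite(moving)), all(is.finite(fixed)))
  out <- .cpp_kabsch(moving, fixed)
  out$translation <- as.numeric(out$translation)
  out
}

#' Closest point on a helical curve to a query point
#'
#' Minimises \code{|query - curve(tau)|} over \code{tau} in
#' \code{phase_window} by dense uniform sampling (512 samples per full turn)
#' followed by golden-section refinement to a phase tolerance of 1e-9.
#'
#' @param curve a \code{\link{helical_curve}}.
#' @param query length-3 point (\enc{Å}{A}).
#' @param phase_window length-2 numeric interval bounding the search.
#' @return list with \code{point} (on the curve), \code{distance}
#'   (\enc{Å}{A}), and \code{phase}.
#' @export
closest_point <- function(curve, query, phase_window) {
  stopifnot(inherits(curve, "helical_curve"))
  query <- as.numeric(query)
  stopifnot(length(query) == 3L, all(is.finite(query)),
            length(phase_window) == 2L, all(is.finite(phase_window)))
  if (phase_window[2] <= phase_window[1])
    stop("empty phase window", call. = FALSE)
  out <- .cpp_closest_point(curve$r, curve$p, curve$t, curve$rotation,
                            curve$origin, query,
                            phase_window[1], phase_window[2],
                            512L, 1e-9)
  out$point <- as.numeric(out$point)
  out[c("point", "distance", "phase")]
}

# Brute-force closest-point scan over n uniform phases (test oracle).
closest_point_brute <- function(curve, query, phase_window, n = 1e6L) {
  .cpp_closest_point_brute(curve$r, curve$p, curve$t, curve$rotation,
                           curve$origin, as.numeric(query),
                           phase_window[1], phase_window[2], as.integer(n))
}

#' Serialise a helical curve to JSON
#'
#' @param curve a \code{\link{helical_curve}}.
#' @return JSON string with fields \code{r}, \code{p}, \code{t},
#'   \code{R} (9 numbers, row-major) and \code{r0} (3 numbers).
#' @export
curve_to_json <- function(curve) {
  stopifnot(inherits(curve, "helical_curve"))
  jsonlite::toJSON(list(r = curve$r, p = curve$p, t = curve$t,
                        R = as.numeric(t(curve$rotation)),
                        r0 = curve$origin),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname curve_to_json
#' @param json JSON string produced by \code{curve_to_json}.
#' @return \code{curve_from_json} returns the reconstructed
#'   \code{helical_curve}.
#' @export
curve_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  helical_curve(x$r, x$p, x$t, matrix(x$R, 3, 3, byrow = TRUE), x$r0)
}
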