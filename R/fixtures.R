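# Deterministic generators for synthetic guide-atom traces: ideal and noisy
# helices (both handednesses, arbitrary placement), kinked helices, an ideal
# B-DNA single-strand P trace, collinear and random-coil controls. All
# randomness flows from the spec's integer seed; generation is a pure
# function of the spec.

#' Specification of a synthetic trace
#'
#' @param kind one of \code{"ideal_protein_helix"}, \code{"ideal_bdna_strand"},
#'   \code{"noisy_helix"}, \code{"kinked_helix"}, \code{"collinear"},
#'   \code{"random_coil"}.
#' @param n_atoms number of guide atoms (>= 4).
#' @param r,p,t helix parameters (radius \enc{Å}{A}, rise \enc{Å}{A}/residue,
#'   signed turn angle rad). Defaults: the canonical alpha-helical C-alpha
#'   geometry (r = 2.3, p = 1.5, t = 1.7453 ~ 100 deg) for protein kinds;
#'   the canonical B-DNA fiber P-trace values (r = 9.4, rise = 3.4,
#'   twist = 36 deg) for \code{"ideal_bdna_strand"}.
#' @param noise_sigma i.i.d. Gaussian positional noise s.d. per coordinate
#'   (\enc{Å}{A}); only \code{"noisy_helix"} uses a nonzero default.
#' @param kink_angle axis kink (radians) for \code{"kinked_helix"}.
#' @param seed integer seed driving placement and noise.
#' @param random_placement apply a seeded random rigid motion (default TRUE).
#' @return An object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(kind = c("ideal_protein_helix", "ideal_bdna_strand",
                                  "noisy_helix", "kinked_helix", "collinear",
                                  "random_coil"),
                         n_atoms = 12L, r = NULL, p = NULL, t = NULL,
                         noise_sigma = NULL, kink_angle = 30 * pi / 180,
                         seed = 1L, random_placement = TRUE) {
  kind <- match.arg(kind)
  if (kind == "ideal_bdna_strand") {
    r <- r %||% 9.4; p <- p %||% 3.4; t <- t %||% (36 * pi / 180)
  } else {
    r <- r %||% 2.3; p <- p %||% 1.5; t <- t %||% 1.7453
  }
  noise_sigma <- noise_sigma %||% if (kind == "noisy_helix") 0.05 else 0
  stopifnot(n_atoms >= 4L, noise_sigma >= 0, is.finite(kink_angle))
  structure(list(kind = kind, n_atoms = as.integer(n_atoms),
                 r = as.numeric(r), p = as.numeric(p), t = as.numeric(t),
                 noise_sigma = as.numeric(noise_sigma),
                 kink_angle = as.numeric(kink_angle),
                 seed = as.integer(seed),
                 random_placement = isTRUE(random_placement)),
            class = "fixture_spec")
}

# seeded uniform random rotation (QR of a Gaussian matrix, det-corrected)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic guide-atom trace
#'
#' Atoms are placed at phases 0, t, 2t, ... of the specified helical curve
#' (exactly the curve parameterisation of \code{\link{helix_points}}), with
#' optional i.i.d. Gaussian noise. The kinked kind concatenates two ideal
#' arcs whose axes differ by \code{kink_angle}; the collinear and
#' random-coil kinds are non-helical controls.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return A \code{\link{helix_trace}} (kind \code{"dna_P"} for
#'   \code{"ideal_bdna_strand"}, \code{"protein_CA"} otherwise), with the
#'   generating \code{spec} and, where defined, the world-frame generating
#'   \code{curve} attached as attributes.
#' @examples
#' tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 8))
#' fit <- helixfit(tr)
#' max(coef(fit)[, "delta"])   # ~0: the fitter recovers the generator
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_atoms
    Q <- if (spec$random_placement) .random_rotation() else diag(3)
    shift <- if (spec$random_placement) stats::runif(3, -20, 20) else c(0, 0, 0)
    curve <- NULL
    base <- switch(
      spec$kind,
      ideal_protein_helix = ,
      ideal_bdna_strand = ,
      noisy_helix = {
        curve <- helical_curve(spec$r, spec$p, spec$t, Q, shift)
        helix_points(curve, spec$t * (seq_len(n) - 1))
      },
      kinked_helix = {
        # one ideal helix whose continuation past the junction atom is
        # rigidly rotated by kink_angle about that atom: both arcs are
        # genuine helices, their axes differ by exactly kink_angle, and the
        # helical phase runs on through the junction
        n1 <- ceiling(n / 2); n2 <- n - n1
        c1 <- helical_curve(spec$r, spec$p, spec$t)
        a <- helix_points(c1, spec$t * (seq_len(n1) - 1))
        cont <- helix_points(c1, spec$t * (n1 - 1 + seq_len(n2)))
        ck <- cos(spec$kink_angle); sk <- sin(spec$kink_angle)
        Rx <- rbind(c(1, 0, 0), c(0, ck, -sk), c(0, sk, ck))
        pivot <- a[n1, ]
        b <- t(Rx %*% (t(cont) - pivot) + pivot)
        pts <- rbind(a, b)
        t(Q %*% t(pts)) + matrix(shift, n, 3, byrow = TRUE)
      },
      collinear = {
        pts <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
        t(Q %*% t(pts)) + matrix(shift, n, 3, byrow = TRUE)
      },
      random_coil = {
        dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        pts <- rbind(0, apply(3.8 * dirs, 2, cumsum))
        t(Q %*% t(pts)) + matrix(shift, n, 3, byrow = TRUE)
      })
    if (spec$noise_sigma > 0)
      base <- base + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma),
                            ncol = 3)
    tr <- helix_trace(base,
                      kind = if (spec$kind == "ideal_bdna_strand") "dna_P"
                      else "protein_CA")
    attr(tr, "spec") <- spec
    attr(tr, "curve") <- curve
    tr
  })
}

#' Read a fixture spec from JSON
#'
#' @param path JSON file with the \code{\link{fixture_spec}} fields.
#' @return A \code{fixture_spec}.
#' @export
read_fixture_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  fixture_spec(kind = x$kind, n_atoms = x$n_atoms %||% 12L, r = x$r,
               p = x$p, t = x$t, noise_sigma = x$noise_sigma,
               kink_angle = x$kink_angle %||% (30 * pi / 180),
               seed = x$seed %||% 1L,
               random_placement = x$random_placement %||% TRUE)
}

#' Specs of the packaged calibration corpus
#'
#' Fifty noisy canonical alpha-helical traces (12 atoms, sigma = 0.05
#' \enc{Å}{A}, seeds 1..50) used to calibrate the shipped default score
#' constants; regenerated identically on demand.
#'
#' @param n number of corpus members (default 50).
#' @param noise_sigma positional noise (default 0.05 \enc{Å}{A}).
#' @return List of \code{\link{fixture_spec}}s.
#' @export
calibration_corpus_specs <- function(n = 50L, noise_sigma = 0.05) {
  lapply(seq_len(n), function(s)
    fixture_spec("noisy_helix", n_atoms = 12L, noise_sigma = noise_sigma,
                 seed = s))
}
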