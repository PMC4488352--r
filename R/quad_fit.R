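# Sliding-window helical-curve fitting: for each quadruple of consecutive
# guide atoms, scan an (r, p) grid centred on the analytic seed, build the
# candidate curve for each grid point, superpose it by SVD and keep the curve
# minimising the closest-point RMSD.

#' Grid-search configuration for quadruple fitting
#'
#' The search scans \code{[r_m - delta_r, r_m + delta_r]} and
#' \code{[p_m - delta_p, p_m + delta_p]} around the analytic seed
#' \code{(r_m, p_m)} with the given step. Defaults: half-widths 0.25 \enc{Å}{A}
#' and step 0.01 \enc{Å}{A} (a 51 x 51 grid).
#'
#' @param delta_r half-width of the radius interval (\enc{Å}{A}).
#' @param delta_p half-width of the rise interval (\enc{Å}{A}).
#' @param step grid spacing for both intervals (\enc{Å}{A}).
#' @return An object of class \code{"fit_config"}.
#' @export
fit_config <- function(delta_r = 0.25, delta_p = 0.25, step = 0.01) {
  stopifnot(is.numeric(delta_r), delta_r > 0,
            is.numeric(delta_p), delta_p > 0,
            is.numeric(step), step > 0)
  if (step > 2 * min(delta_r, delta_p))
    stop("step must be <= 2 * min(delta_r, delta_p)", call. = FALSE)
  structure(list(delta_r = delta_r, delta_p = delta_p, step = step),
            class = "fit_config")
}

#' Fit a helical curve to one quadruple of guide atoms
#'
#' Runs the exhaustive grid search: for every grid point \code{(r, p)} the
#' turn angle follows from \code{\link{turn_angle}} using the mean of the
#' three consecutive inter-atom distances; the 4-point ideal helix at phases
#' \code{(0, t, 2t, 3t)} is superposed onto the quadruple by SVD
#' (\code{\link{superpose}}); the closest-point RMSD ranks grid points
#' (first strict minimum wins, scanning r then p in ascending order).
#' Infeasible grid points (negative radius, \code{d^2 < p^2}, arcsin argument
#' above 1) are skipped.
#'
#' @param quadruple 4x3 matrix of positions (\enc{Å}{A}) in chain order.
#' @param config a \code{\link{fit_config}}.
#' @param window_start identifier attached to the fit (defaults to 1).
#' @return An object of class \code{"quad_fit"}: list with \code{curve}
#'   (\code{\link{helical_curve}}), \code{delta} (closest-point RMSD,
#'   \enc{Å}{A}), \code{corr_rmsd} (corresponded SVD RMSD),
#'   \code{atom_phases} (phases of the atoms' closest points, monotone along
#'   the chain), \code{atom_dists}, \code{seed} and \code{window_start}.
#' @examples
#' quad <- helix_points(helical_curve(2.3, 1.5, 1.7453), 1.7453 * 0:3)
#' fit <- fit_quadruple(quad)
#' fit$delta      # ~0 on an exact helix
#' @export
fit_quadruple <- function(quadruple, config = fit_config(), window_start = 1L) {
  quadruple <- as.matrix(quadruple)
  stopifnot(inherits(config, "fit_config"),
            nrow(quadruple) == 4L, ncol(quadruple) == 3L)
  seed <- seed_params(quadruple)   # errors on degenerate geometry
  res <- .cpp_fit_quadruple(quadruple, seed$r, seed$p,
                            if (seed$t >= 0) 1 else -1,
                            config$delta_r, config$delta_p, config$step,
                            96L, 512L, 1e-9)
  if (!isTRUE(res$ok))
    stop("no feasible (r, p) grid point for this quadruple", call. = FALSE)
  curve <- helical_curve(res$r, res$p, res$t, res$rotation,
                         as.numeric(res$origin))
  structure(list(window_start = window_start,
                 curve = curve,
                 delta = res$delta,
                 corr_rmsd = res$corr_rmsd,
                 atom_phases = as.numeric(res$atom_phases),
                 atom_dists = as.numeric(res$atom_dists),
                 seed = seed,
                 atoms = quadruple),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf(
    "Quadruple fit @ %s: r = %.4f, rise = %.4f, t = %.2f deg, delta = %.6f A\n",
    format(x$window_start), x$curve$r, x$curve$p,
    x$curve$t * 180 / pi, x$delta))
  invisible(x)
}

#' Fit helical curves along a guide-atom trace
#'
#' The central fitting function: slides a window of four consecutive guide
#' atoms along a trace and fits each quadruple with \code{\link{fit_quadruple}}.
#' With \code{stride3 = TRUE} (DNA) the working atom list is decimated to
#' atoms 1, 4, 7, ... so the per-atom turn angle approaches that of a protein
#' helix.
#'
#' @param trace a \code{\link{helix_trace}} (or a plain n x 3 coordinate
#'   matrix, converted via \code{\link{helix_trace}}).
#' @param config a \code{\link{fit_config}}.
#' @param stride3 logical; decimate the trace by 3 before fitting (DNA).
#' @param m samples per inter-atom segment used by \code{\link{predict.helixfit}}
#'   and \code{\link{build_model}} (default 16).
#' @return An object of class \code{"helixfit"}: list with \code{fits}
#'   (one \code{quad_fit} per usable window, NULL at degenerate windows),
#'   \code{gaps} (data.frame of skipped windows and reasons), \code{trace},
#'   \code{working} (the possibly decimated coordinates), \code{stride3},
#'   \code{config}. Supports \code{coef}, \code{summary}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot} and \code{simulate}.
#' @examples
#' tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 8))
#' fit <- helixfit(tr)
#' coef(fit)
#' @export
helixfit <- function(trace, config = fit_config(), stride3 = FALSE, m = 16L) {
  if (!inherits(trace, "helix_trace")) trace <- helix_trace(trace)
  stopifnot(inherits(config, "fit_config"))
  xyz <- trace$xyz
  idx <- seq_len(nrow(xyz))
  if (stride3) idx <- idx[seq(1L, nrow(xyz), by = 3L)]
  work <- xyz[idx, , drop = FALSE]
  n <- nrow(work)
  gaps <- data.frame(window = integer(), reason = character())
  fits <- list()
  if (n < 4L) {
    warning(sprintf("trace too short to fit (%d working atoms, need >= 4)", n))
    return(structure(list(fits = fits, gaps = gaps, trace = trace,
                          working = work, working_index = idx,
                          stride3 = stride3, config = config, m = m),
                     class = "helixfit"))
  }
  for (i in seq_len(n - 3L)) {
    quad <- work[i:(i + 3L), , drop = FALSE]
    f <- tryCatch(fit_quadruple(quad, config, window_start = i),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      gaps <- rbind(gaps, data.frame(window = i, reason = f))
      fits[i] <- list(NULL)
    } else {
      fits[[i]] <- f
    }
  }
  structure(list(fits = fits, gaps = gaps, trace = trace, working = work,
                 working_index = idx, stride3 = stride3, config = config,
                 m = m),
            class = "helixfit")
}

# windows that produced a fit
good_fits <- function(object) {
  Filter(Negate(is.null), object$fits)
}

#' @export
print.helixfit <- function(x, ...) {
  nf <- length(good_fits(x))
  cat(sprintf("Polyhelix fit: chain %s (%s), %d atoms%s, %d fitted windows",
              x$trace$chain %||% "?", x$trace$kind,
              nrow(x$trace$xyz),
              if (x$stride3) sprintf(" (stride-3: %d working)",
                                     nrow(x$working)) else "",
              nf))
  if (nrow(x$gaps)) cat(sprintf(", %d degenerate windows", nrow(x$gaps)))
  cat("\n")
  if (nf) {
    cf <- coef(x)
    cat(sprintf("  median r = %.3f A, rise = %.3f A, t = %.1f deg, delta = %.4f A\n",
                stats::median(cf[, "r"]), stats::median(cf[, "p"]),
                stats::median(cf[, "t"]) * 180 / pi,
                stats::median(cf[, "delta"])))
  }
  invisible(x)
}

#' Extract per-window helix parameters
#'
#' @param object a \code{\link{helixfit}} object.
#' @param ... unused.
#' @return Matrix with one row per fitted window and columns \code{window}
#'   (working-atom index of the window start), \code{r}, \code{p}, \code{t}
#'   (radians, signed), \code{delta}.
#' @export
coef.helixfit <- function(object, ...) {
  gf <- good_fits(object)
  out <- t(vapply(gf, function(f)
    c(window = f$window_start, r = f$curve$r, p = f$curve$p,
      t = f$curve$t, delta = f$delta), numeric(5)))
  rownames(out) <- NULL
  out
}

#' @export
summary.helixfit <- function(object, score_params = NULL, ...) {
  cf <- coef(object)
  scores <- if (object$trace$kind == "protein_CA" && nrow(cf))
    helix_scores(object, score_params %||% default_score_params())
  else NULL
  structure(list(fit = object, coef = cf, scores = scores),
            class = "summary.helixfit")
}

#' @export
print.summary.helixfit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$coef)) {
    cat("Per-window parameters:\n")
    cf <- x$coef
    cf[, "t"] <- cf[, "t"] * 180 / pi
    colnames(cf) <- c("window", "r (A)", "rise (A)", "t (deg)", "delta (A)")
    print(round(cf, 4))
  }
  if (!is.null(x$scores)) {
    cat("Helix scores (vs standard protein helix):\n")
    print(data.frame(window = x$scores$window,
                     h = round(x$scores$h, 4), bin = x$scores$bin))
  }
  invisible(x)
}

#' Sampled model curve for a fitted trace
#'
#' @param object a \code{\link{helixfit}} object.
#' @param m samples per inter-atom segment.
#' @param ... unused.
#' @return The averaged \code{\link{build_model}} curve's samples as one
#'   matrix (segments concatenated, shared endpoints deduplicated).
#' @export
predict.helixfit <- function(object, m = object$m, ...) {
  model <- build_model(object, m = m)
  model_samples(model)
}

#' @export
fitted.helixfit <- function(object, ...) {
  # closest point on the averaged model curve for each working atom
  model <- build_model(object, m = object$m)
  det <- detachment(object$working, model, thickness = Inf)
  attr(det, "closest")
}

#' Per-atom distances to the averaged model curve
#'
#' @param object a \code{\link{helixfit}} object.
#' @param ... unused.
#' @return Numeric vector: for each working atom, the minimum distance
#'   (\enc{Å}{A}) to the sampled model curve (NA for atoms not covered).
#' @export
residuals.helixfit <- function(object, ...) {
  model <- build_model(object, m = object$m)
  detachment(object$working, model, thickness = Inf)$distance
}

#' @export
plot.helixfit <- function(x, score_params = NULL, ...) {
  cf <- coef(x)
  if (!nrow(cf)) {
    warning("nothing to plot: no fitted windows")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cf[, "window"], cf[, "delta"], type = "b", pch = 16,
                 xlab = "window start (working atom)",
                 ylab = expression(Delta ~ "(A)"),
                 main = "Closest-point RMSD per window", ...)
  if (x$trace$kind == "protein_CA") {
    sc <- helix_scores(x, score_params %||% default_score_params())
    cols <- score_bin_colors()[sc$bin]
    graphics::plot(sc$window, sc$h, type = "h", lwd = 3, col = cols,
                   xlab = "window start (working atom)", ylab = "helix score",
                   main = "Deviation from the standard protein helix")
  } else {
    graphics::plot(cf[, "window"], cf[, "t"] * 180 / pi, type = "b", pch = 16,
                   xlab = "window start (working atom)",
                   ylab = "turn angle (deg)", main = "Turn angle per window")
  }
  invisible(x)
}

#' Simulate noisy traces from a fitted model
#'
#' Draws guide-atom traces by adding i.i.d. Gaussian noise to the fitted
#' model curve's closest points to the working atoms.
#'
#' @param object a \code{\link{helixfit}} object.
#' @param nsim number of traces.
#' @param seed optional integer seed.
#' @param sigma noise s.d. per coordinate (\enc{Å}{A}); defaults to the mean
#'   fitted delta.
#' @param ... unused.
#' @return List of n x 3 coordinate matrices.
#' @export
simulate.helixfit <- function(object, nsim = 1, seed = NULL, sigma = NULL,
                              ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  base <- fitted(object)
  cf <- coef(object)
  if (is.null(sigma)) sigma <- if (nrow(cf)) mean(cf[, "delta"]) else 0
  lapply(seq_len(nsim), function(i)
    base + matrix(stats::rnorm(length(base), 0, sigma), ncol = 3))
}

#' Serialise fits to JSON lines
#'
#' One JSON object per fitted window: chain, window_start, r, p, t_rad,
#' t_deg, delta, R (row-major), r0, axis, center.
#'
#' @param object a \code{\link{helixfit}} object.
#' @param path destination file.
#' @return Invisibly, the path.
#' @export
write_fits_jsonl <- function(object, path) {
  stopifnot(inherits(object, "helixfit"))
  lines <- vapply(good_fits(object), function(f) {
    jsonlite::toJSON(list(
      chain = object$trace$chain %||% "",
      window_start = f$window_start,
      r = f$curve$r, p = f$curve$p,
      t_rad = f$curve$t, t_deg = f$curve$t * 180 / pi,
      delta = f$delta,
      R = as.numeric(t(f$curve$rotation)),
      r0 = f$curve$origin,
      axis = helix_axis(f$curve),
      center = f$curve$origin), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read fits back from JSON lines
#'
#' @param path file written by \code{\link{write_fits_jsonl}}.
#' @return List of \code{quad_fit}-like records (window_start, curve, delta).
#' @export
read_fits_jsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    list(window_start = x$window_start,
         curve = helical_curve(x$r, x$p, x$t_rad,
                               matrix(x$R, 3, 3, byrow = TRUE), x$r0),
         delta = x$delta, chain = x$chain)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
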