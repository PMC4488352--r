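# Merging the per-window helical curves into one C0-continuous model curve
# (pointwise averaging of overlapping window segments) and the helix center
# polyline connecting successive window-curve centers.

#' Sample one inter-atom segment of a fitted window curve
#'
#' @param fit a \code{\link{fit_quadruple}} result.
#' @param from_phase,to_phase phase bounds, normally two consecutive entries
#'   of \code{fit$atom_phases}; \code{from_phase < to_phase} required.
#' @param m number of samples (>= 2), uniform in phase.
#' @return m x 3 matrix of points on the fitted curve.
#' @export
curve_segment <- function(fit, from_phase, to_phase, m = 16L) {
  stopifnot(inherits(fit, "quad_fit"), m >= 2L)
  if (from_phase >= to_phase)
    stop("from_phase must be < to_phase", call. = FALSE)
  helix_points(fit$curve, seq(from_phase, to_phase, length.out = m))
}

#' Build the averaged model curve from a trace's window fits
#'
#' For every pair of consecutive working atoms (a_i, a_(i+1)), each window
#' curve covering that pair contributes its own segment between the two
#' atoms' closest-point phases; the model segment is the pointwise average
#' of the contributors' samples (corresponded by uniform index). Interior
#' pairs collect 3 contributors, the first and last 1, the second and
#' second-to-last 2 — degenerate windows reduce the count for the segments
#' they would cover. Shared endpoints of adjacent segments are unified to
#' their mean afterwards, so the model is C0-continuous by construction.
#'
#' @param object a \code{\link{helixfit}} object.
#' @param m samples per inter-atom segment (>= 2).
#' @return An object of class \code{"model_curve"}: list with
#'   \code{segments} (one m x 3 matrix per atom pair; NULL where no window
#'   covers the pair), \code{contributors} (count per segment), \code{m},
#'   and \code{atoms} (the working coordinates).
#' @export
build_model <- function(object, m = 16L) {
  stopifnot(inherits(object, "helixfit"), m >= 2L)
  work <- object$working
  n <- nrow(work)
  nwin <- max(0L, n - 3L)
  nseg <- max(0L, n - 1L)
  segments <- vector("list", nseg)
  contributors <- integer(nseg)
  if (nseg > 0L && nwin > 0L) {
    for (i in seq_len(nseg)) {
      js <- seq(max(1L, i - 2L), min(i, nwin))
      acc <- NULL
      cnt <- 0L
      for (j in js) {
        f <- if (j <= length(object$fits)) object$fits[[j]] else NULL
        if (is.null(f)) next
        k <- i - j + 1L   # local atom index of a_i within window j (1..3)
        ph <- seq(f$atom_phases[k], f$atom_phases[k + 1L], length.out = m)
        pts <- helix_points(f$curve, ph)
        acc <- if (is.null(acc)) pts else acc + pts
        cnt <- cnt + 1L
      }
      contributors[i] <- cnt
      segments[[i]] <- if (cnt > 0L) acc / cnt else NULL
    }
    # unify shared endpoints of adjacent non-missing segments
    for (i in seq_len(nseg - 1L)) {
      if (is.null(segments[[i]]) || is.null(segments[[i + 1L]])) next
      shared <- (segments[[i]][m, ] + segments[[i + 1L]][1L, ]) / 2
      segments[[i]][m, ] <- shared
      segments[[i + 1L]][1L, ] <- shared
    }
  }
  structure(list(segments = segments, contributors = contributors, m = m,
                 atoms = work, kind = object$trace$kind,
                 chain = object$trace$chain),
            class = "model_curve")
}

#' @export
print.model_curve <- function(x, ...) {
  cat(sprintf(
    "Model curve: %d segments (%d covered), %d samples/segment\n",
    length(x$segments), sum(x$contributors > 0), x$m))
  invisible(x)
}

#' Concatenated samples of a model curve
#'
#' @param model a \code{\link{build_model}} result.
#' @return One matrix of samples in chain order; shared endpoints between
#'   contiguous segments appear once.
#' @export
model_samples <- function(model) {
  stopifnot(inherits(model, "model_curve"))
  out <- NULL
  prev_covered <- FALSE
  for (i in seq_along(model$segments)) {
    seg <- model$segments[[i]]
    if (is.null(seg)) { prev_covered <- FALSE; next }
    add <- if (prev_covered) seg[-1L, , drop = FALSE] else seg
    out <- rbind(out, add)
    prev_covered <- TRUE
  }
  if (is.null(out)) matrix(numeric(), 0L, 3L) else out
}

#' Export a model curve as JSON or pseudo-atom PDB
#'
#' @param model a \code{\link{build_model}} result.
#' @param path destination.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "model_curve"))
  jsonlite::write_json(
    list(m = model$m, contributors = model$contributors,
         segments = lapply(model$segments, function(s)
           if (is.null(s)) NULL else unname(s))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
write_model_pdb <- function(model, path) {
  write_trace_pdb(model_samples(model), path,
                  chain = substr(model$chain %||% "A", 1, 1), het = TRUE)
  invisible(path)
}

#' Helix center polyline
#'
#' Connects the centers (placement origins) of successive window curves.
#' For a genuine helical curve all centers lie on the axis, so the polyline
#' is a straight line; bends flag local deviations such as kinks.
#'
#' @param object a \code{\link{helixfit}} object (or list of
#'   \code{quad_fit}s).
#' @param max_delta optional quality cutoff (\enc{Å}{A}): windows whose
#'   closest-point RMSD exceeds it are dropped before connecting centers.
#'   The center of a curve that does not actually fit its atoms carries no
#'   geometric meaning, so kink/bend measurements use a cutoff of about
#'   0.08 \enc{Å}{A} (the upper delta of genuinely helical residues); the
#'   default \code{Inf} keeps one vertex per fit.
#' @return An object of class \code{"center_polyline"}: list with
#'   \code{vertices} (one row per kept fit) and \code{bend_angles} (radians,
#'   one per interior vertex; empty for < 3 vertices).
#' @export
center_polyline <- function(object, max_delta = Inf) {
  fits <- if (inherits(object, "helixfit")) good_fits(object) else object
  fits <- Filter(function(f) f$delta <= max_delta, fits)
  if (!length(fits)) stop("no fits to connect", call. = FALSE)
  v <- t(vapply(fits, function(f) f$curve$origin, numeric(3)))
  bends <- numeric(0)
  if (nrow(v) >= 3L) {
    e <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
    len <- sqrt(rowSums(e^2))
    bends <- vapply(seq_len(nrow(e) - 1L), function(k) {
      if (len[k] < 1e-12 || len[k + 1L] < 1e-12) return(0)
      cosang <- sum(e[k, ] * e[k + 1L, ]) / (len[k] * len[k + 1L])
      acos(max(-1, min(1, cosang)))
    }, numeric(1))
  }
  structure(list(vertices = v, bend_angles = bends),
            class = "center_polyline")
}

#' @export
print.center_polyline <- function(x, ...) {
  cat(sprintf("Helix center polyline: %d vertices", nrow(x$vertices)))
  if (length(x$bend_angles))
    cat(sprintf(", max bend %.2f deg", max(x$bend_angles) * 180 / pi))
  cat("\n")
  invisible(x)
}
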