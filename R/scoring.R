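# Per-residue helix score: the product of squared standardized deviations of
# (r, p, t, delta) from the standard protein helix, score bins for coloring,
# and calibration of the normal-distribution constants from a corpus of fits.

#' Normal-distribution constants of the standard protein helix
#'
#' The means (mu_r, mu_p, mu_t) define the standard protein helix; the sigmas
#' scale each deviation term of the helix score. \code{t_unit} declares the
#' unit mu_t/sigma_t are given in; values are stored in radians.
#'
#' @param mu_r,sigma_r radius mean and s.d. (\enc{Å}{A}).
#' @param mu_p,sigma_p rise mean and s.d. (\enc{Å}{A}/residue).
#' @param mu_t,sigma_t turn-angle mean and s.d. (unit per \code{t_unit}).
#' @param sigma_delta s.d. of the closest-point RMSD (\enc{Å}{A}). No
#'   mu_delta exists: the score's RMSD term is \eqn{\Delta^2/(2\sigma_\Delta^2)}.
#' @param t_unit \code{"radians"} or \code{"degrees"} (converted on input).
#' @return An object of class \code{"score_params"}.
#' @export
score_params <- function(mu_r, sigma_r, mu_p, sigma_p, mu_t, sigma_t,
                         sigma_delta, t_unit = c("radians", "degrees")) {
  t_unit <- match.arg(t_unit)
  if (t_unit == "degrees") {
    mu_t <- mu_t * pi / 180
    sigma_t <- sigma_t * pi / 180
  }
  vals <- c(mu_r, sigma_r, mu_p, sigma_p, mu_t, sigma_t, sigma_delta)
  stopifnot(all(is.finite(vals)))
  if (min(sigma_r, sigma_p, sigma_t, sigma_delta) <= 0)
    stop("all sigmas must be > 0", call. = FALSE)
  structure(list(mu_r = mu_r, sigma_r = sigma_r, mu_p = mu_p,
                 sigma_p = sigma_p, mu_t = mu_t, sigma_t = sigma_t,
                 sigma_delta = sigma_delta),
            class = "score_params")
}

#' @export
print.score_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Standard protein helix constants:\n",
    "  r: %.4f +/- %.4f A\n  rise: %.4f +/- %.4f A\n",
    "  t: %.4f +/- %.4f rad (%.2f +/- %.2f deg)\n  delta: +/- %.4f A\n"),
    x$mu_r, x$sigma_r, x$mu_p, x$sigma_p, x$mu_t, x$sigma_t,
    x$mu_t * 180 / pi, x$sigma_t * 180 / pi, x$sigma_delta))
  invisible(x)
}

#' Helix score of one fitted window
#'
#' The score of residue i (the window's first residue, covering residues
#' i..i+3) is the product
#' \deqn{h_i = \frac{(r_i-\mu_r)^2}{2\sigma_r^2} \times
#'   \frac{(p_i-\mu_p)^2}{2\sigma_p^2} \times
#'   \frac{(t_i-\mu_t)^2}{2\sigma_t^2} \times
#'   \frac{\Delta_i^2}{2\sigma_\Delta^2}.}
#' It is zero whenever any single parameter matches its mean, and grows with
#' joint deviation from the standard protein helix. The last three residues
#' of a chain head no window and receive no score. Turn angles are compared
#' by magnitude-preserving signed values (a left-handed window scores high
#' against right-handed means through its large t deviation).
#'
#' @param fit a \code{\link{fit_quadruple}} result.
#' @param params a \code{\link{score_params}}.
#' @return list with \code{h} (nonnegative) and \code{bin}
#'   (see \code{\link{score_bin}}).
#' @export
helix_score <- function(fit, params = default_score_params()) {
  stopifnot(inherits(fit, "quad_fit"), inherits(params, "score_params"))
  h <- ((fit$curve$r - params$mu_r)^2 / (2 * params$sigma_r^2)) *
       ((fit$curve$p - params$mu_p)^2 / (2 * params$sigma_p^2)) *
       ((fit$curve$t - params$mu_t)^2 / (2 * params$sigma_t^2)) *
       (fit$delta^2 / (2 * params$sigma_delta^2))
  list(h = h, bin = score_bin(h))
}

#' Helix scores for all fitted windows of a trace
#'
#' @param object a \code{\link{helixfit}} object.
#' @param params a \code{\link{score_params}}.
#' @return data.frame with columns \code{window} (working-atom index of the
#'   window's first residue), \code{residue} (author residue number),
#'   \code{h}, \code{bin}.
#' @export
helix_scores <- function(object, params = default_score_params()) {
  stopifnot(inherits(object, "helixfit"))
  gf <- good_fits(object)
  if (!length(gf))
    return(data.frame(window = integer(), residue = integer(),
                      h = numeric(), bin = character()))
  h <- vapply(gf, function(f) helix_score(f, params)$h, numeric(1))
  win <- vapply(gf, function(f) f$window_start, numeric(1))
  data.frame(window = win,
             residue = object$trace$resno[object$working_index[win]],
             h = h, bin = score_bin(h))
}

.bin_levels <- c("green", "celeste", "yellow", "magenta", "red")
.bin_breaks <- c(20, 50, 100, 200)

#' Score bin of a helix score
#'
#' Bins: [0, 20] green, (20, 50] celeste, (50, 100] yellow, (100, 200]
#' magenta, (200, Inf) red.
#'
#' @param h nonnegative helix score(s).
#' @return Ordered factor with levels green < celeste < yellow < magenta
#'   < red.
#' @export
score_bin <- function(h) {
  stopifnot(is.numeric(h), all(is.finite(h)))
  if (any(h < 0)) stop("helix score must be nonnegative", call. = FALSE)
  # a threshold value itself stays in the lower bin (right-closed intervals)
  idx <- 1L + rowSums(outer(h, .bin_breaks, `>`))
  factor(.bin_levels[idx], levels = .bin_levels, ordered = TRUE)
}

#' RGB colors of the score bins
#'
#' @return Named character vector of hex colors for the five bins.
#' @export
score_bin_colors <- function() {
  c(green = "#00CC00", celeste = "#66CCFF", yellow = "#FFFF00",
    magenta = "#FF00FF", red = "#FF0000")
}

#' Calibrate score constants from a corpus of fits
#'
#' Means and standard deviations of r, p, t over the corpus become
#' (mu, sigma); sigma_delta is the standard deviation of delta.
#'
#' @param fits list of \code{\link{fit_quadruple}} results (or
#'   \code{helixfit} objects, whose fitted windows are pooled); at least 30.
#' @return A \code{\link{score_params}}.
#' @export
calibrate_score_params <- function(fits) {
  pool <- list()
  for (f in fits) {
    if (inherits(f, "helixfit")) pool <- c(pool, good_fits(f))
    else if (inherits(f, "quad_fit")) pool <- c(pool, list(f))
    else stop("fits must be quad_fit or helixfit objects", call. = FALSE)
  }
  if (length(pool) < 30L)
    stop(sprintf("calibration needs >= 30 fits, got %d", length(pool)),
         call. = FALSE)
  r <- vapply(pool, function(f) f$curve$r, numeric(1))
  p <- vapply(pool, function(f) f$curve$p, numeric(1))
  t <- vapply(pool, function(f) f$curve$t, numeric(1))
  d <- vapply(pool, function(f) f$delta, numeric(1))
  sds <- c(stats::sd(r), stats::sd(p), stats::sd(t), stats::sd(d))
  if (min(sds) <= 0 || any(!is.finite(sds)))
    stop("degenerate corpus: a parameter has zero spread", call. = FALSE)
  score_params(mean(r), sds[1], mean(p), sds[2], mean(t), sds[3], sds[4])
}

#' Read/write score constants as JSON
#'
#' JSON fields: mu_r, sigma_r, mu_p, sigma_p, mu_t, sigma_t, sigma_delta,
#' t_unit.
#'
#' @param params a \code{\link{score_params}}.
#' @param path file path.
#' @return \code{read_score_params} returns a \code{score_params};
#'   \code{write_score_params} the path, invisibly.
#' @export
write_score_params <- function(params, path) {
  stopifnot(inherits(params, "score_params"))
  jsonlite::write_json(c(unclass(params), list(t_unit = "radians")), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_params
#' @export
read_score_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  score_params(x$mu_r, x$sigma_r, x$mu_p, x$sigma_p, x$mu_t, x$sigma_t,
               x$sigma_delta, t_unit = x$t_unit %||% "radians")
}

.helixfit_env <- new.env(parent = emptyenv())

#' Default score constants
#'
#' The constants shipped with the package, calibrated with
#' \code{\link{calibrate_score_params}} on the packaged synthetic corpus of
#' 50 noisy alpha-helical traces (see \code{scripts/make_default_params.R}
#' in the source tree). They are surrogates for constants derived from a
#' curated PDB survey, which no public table provides; supply your own via
#' \code{\link{read_score_params}} for production scoring.
#'
#' @return A \code{\link{score_params}}.
#' @export
default_score_params <- function() {
  if (is.null(.helixfit_env$default_params)) {
    path <- system.file("extdata", "default_score_params_synthetic.json",
                        package = "helixfit", mustWork = TRUE)
    .helixfit_env$default_params <- read_score_params(path)
  }
  .helixfit_env$default_params
}
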