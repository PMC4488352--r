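# Score-colored ribbon meshes swept along the model curve, the per-atom
# detachment diagnostic, the choppiness (curvature-jump) metric, and a cubic
# Hermite (Catmull-Rom) baseline used ONLY as the comparison reference for
# those metrics -- it is not a modelling path of this package.

# samples of a model plus the segment index each sample belongs to
.model_samples_indexed <- function(model) {
  pts <- NULL
  seg_of <- integer(0)
  prev_covered <- FALSE
  for (i in seq_along(model$segments)) {
    seg <- model$segments[[i]]
    if (is.null(seg)) { prev_covered <- FALSE; next }
    add <- if (prev_covered) seg[-1L, , drop = FALSE] else seg
    pts <- rbind(pts, add)
    seg_of <- c(seg_of, rep(i, nrow(add)))
    prev_covered <- TRUE
  }
  list(points = pts, segment = seg_of)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 0) else v / n
}

#' Build a score-colored ribbon mesh along the model curve
#'
#' A flat rectangular strip is swept along the model samples. At each sample
#' the strip's in-plane (width) direction points from the sample toward the
#' local helix axis (the covering window curve's axis line), orthogonalized
#' against the curve tangent and sign-continued along the strip; the
#' thickness direction completes the frame. Each sample contributes 8
#' vertices (the 4 cross-section corners, duplicated so the four side strips
#' carry flat per-face normals); the ends are capped.
#'
#' @param model a \code{\link{build_model}} result.
#' @param object the \code{\link{helixfit}} the model came from (supplies
#'   the per-window axes).
#' @param scores optional \code{\link{helix_scores}} data.frame; NULL (DNA)
#'   colors the whole ribbon green.
#' @param width ribbon width (\enc{Å}{A}).
#' @param thickness ribbon thickness (\enc{Å}{A}); must be < width.
#' @return An object of class \code{"ribbon_mesh"}: \code{vertices} (V x 3),
#'   \code{normals} (V x 3, unit), \code{faces} (F x 3, 1-based),
#'   \code{colors} (V x 3, 0-255 RGB).
#' @export
build_ribbon <- function(model, object, scores = NULL, width = 2.0,
                         thickness = 0.5) {
  stopifnot(inherits(model, "model_curve"), inherits(object, "helixfit"),
            width > thickness, thickness > 0)
  ms <- .model_samples_indexed(model)
  pts <- ms$points
  ns <- if (is.null(pts)) 0L else nrow(pts)
  if (ns < 2L)
    return(structure(list(vertices = matrix(numeric(), 0, 3),
                          normals = matrix(numeric(), 0, 3),
                          faces = matrix(integer(), 0, 3),
                          colors = matrix(integer(), 0, 3)),
                     class = "ribbon_mesh"))
  nwin <- length(object$fits)
  axis_of_segment <- function(i) {
    js <- seq(max(1L, i - 2L), min(i, nwin))
    js <- rev(js)[order(abs(rev(js) - (i - 1L)))]  # prefer middle contributor
    for (j in js) {
      f <- object$fits[[j]]
      if (!is.null(f)) return(list(o = f$curve$origin,
                                   n = helix_axis(f$curve)))
    }
    NULL
  }
  # per-sample frames
  U <- B <- Tg <- matrix(0, ns, 3)
  for (s in seq_len(ns)) {
    tg <- .unit(if (s == 1L) pts[2, ] - pts[1, ]
                else if (s == ns) pts[ns, ] - pts[ns - 1L, ]
                else pts[s + 1L, ] - pts[s - 1L, ])
    ax <- axis_of_segment(ms$segment[s])
    u <- c(0, 0, 0)
    if (!is.null(ax)) {
      w <- pts[s, ] - ax$o
      foot <- ax$o + sum(w * ax$n) * ax$n    # projection onto the axis line
      u <- foot - pts[s, ]
    }
    u <- u - sum(u * tg) * tg
    if (sqrt(sum(u^2)) < 1e-9) {             # degenerate: any normal will do
      u <- c(-tg[2], tg[1], 0)
      if (sqrt(sum(u^2)) < 1e-9) u <- c(0, -tg[3], tg[2])
    }
    u <- .unit(u)
    if (s > 1L && sum(u * U[s - 1L, ]) < 0) u <- -u   # sign continuity
    b <- .unit(c(tg[2] * u[3] - tg[3] * u[2],
                 tg[3] * u[1] - tg[1] * u[3],
                 tg[1] * u[2] - tg[2] * u[1]))
    U[s, ] <- u; B[s, ] <- b; Tg[s, ] <- tg
  }
  # colors: one bin color per sample from its segment's first residue
  cols <- matrix(rep(grDevices::col2rgb(score_bin_colors()[["green"]]),
                     ns), ns, 3, byrow = TRUE)
  if (!is.null(scores) && nrow(scores)) {
    hexmap <- score_bin_colors()
    for (s in seq_len(ns)) {
      i <- ms$segment[s]
      row <- scores[scores$window <= i, , drop = FALSE]
      if (nrow(row)) {
        bin <- as.character(row$bin[which.max(row$window)])
        cols[s, ] <- as.integer(grDevices::col2rgb(hexmap[[bin]]))
      }
    }
  }
  hw <- width / 2; ht <- thickness / 2
  # 8 vertices per sample: pairs for the +b, -b, +u, -u side strips
  corner <- function(su, sb) pts + su * hw * U + sb * ht * B
  c_pp <- corner(+1, +1); c_mp <- corner(-1, +1)
  c_pm <- corner(+1, -1); c_mm <- corner(-1, -1)
  V <- matrix(0, 8L * ns, 3)
  N <- matrix(0, 8L * ns, 3)
  for (s in seq_len(ns)) {
    o <- (s - 1L) * 8L
    V[o + 1L, ] <- c_pp[s, ]; N[o + 1L, ] <- B[s, ]    # top strip
    V[o + 2L, ] <- c_mp[s, ]; N[o + 2L, ] <- B[s, ]
    V[o + 3L, ] <- c_pm[s, ]; N[o + 3L, ] <- -B[s, ]   # bottom strip
    V[o + 4L, ] <- c_mm[s, ]; N[o + 4L, ] <- -B[s, ]
    V[o + 5L, ] <- c_pp[s, ]; N[o + 5L, ] <- U[s, ]    # +u edge strip
    V[o + 6L, ] <- c_pm[s, ]; N[o + 6L, ] <- U[s, ]
    V[o + 7L, ] <- c_mp[s, ]; N[o + 7L, ] <- -U[s, ]   # -u edge strip
    V[o + 8L, ] <- c_mm[s, ]; N[o + 8L, ] <- -U[s, ]
  }
  colsV <- cols[rep(seq_len(ns), each = 8L), , drop = FALSE]
  faces <- list()
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  for (s in seq_len(ns - 1L)) {
    o1 <- (s - 1L) * 8L; o2 <- s * 8L
    faces[[length(faces) + 1L]] <- rbind(
      quad(o1 + 1L, o1 + 2L, o2 + 2L, o2 + 1L),   # top
      quad(o1 + 4L, o1 + 3L, o2 + 3L, o2 + 4L),   # bottom
      quad(o1 + 6L, o1 + 5L, o2 + 5L, o2 + 6L),   # +u side
      quad(o1 + 7L, o1 + 8L, o2 + 8L, o2 + 7L))   # -u side
  }
  # end caps over the first and last cross-sections
  faces[[length(faces) + 1L]] <- quad(1L, 2L, 4L, 3L)
  oL <- (ns - 1L) * 8L
  faces[[length(faces) + 1L]] <- quad(oL + 3L, oL + 4L, oL + 2L, oL + 1L)
  structure(list(vertices = V, normals = N,
                 faces = do.call(rbind, faces),
                 colors = colsV),
            class = "ribbon_mesh")
}

#' @export
print.ribbon_mesh <- function(x, ...) {
  cat(sprintf("Ribbon mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# minimum distance from point q to the polyline through pts, plus the foot
.point_polyline <- function(q, pts) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  ab <- b - a
  aq <- sweep(a, 2, q, function(x, y) y - x)   # q - a
  tt <- rowSums(aq * ab) / pmax(rowSums(ab^2), 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  foot <- a + ab * tt
  d2 <- rowSums(sweep(foot, 2, q)^2)
  k <- which.min(d2)
  list(distance = sqrt(d2[k]), closest = foot[k, ])
}

#' Per-atom detachment from the model curve
#'
#' A guide atom is detached when it lies outside the ribbon's thickness
#' envelope, i.e. farther from the model polyline than thickness/2.
#'
#' @param atoms a \code{\link{helix_trace}} or n x 3 coordinate matrix.
#' @param model a \code{\link{build_model}} result (or any object with
#'   polyline samples via \code{\link{model_samples}}).
#' @param thickness ribbon thickness (\enc{Å}{A}).
#' @return data.frame with per-atom \code{distance} (\enc{Å}{A}) and
#'   \code{detached} flag; the closest model points are attached as the
#'   n x 3 \code{"closest"} attribute.
#' @export
detachment <- function(atoms, model, thickness = 0.5) {
  if (inherits(atoms, "helix_trace")) atoms <- atoms$xyz
  atoms <- as.matrix(atoms)
  pts <- model_samples(model)
  if (nrow(pts) < 2L) stop("model has no usable samples", call. = FALSE)
  hits <- lapply(seq_len(nrow(atoms)), function(i)
    .point_polyline(atoms[i, ], pts))
  d <- vapply(hits, `[[`, numeric(1), "distance")
  out <- data.frame(atom = seq_len(nrow(atoms)), distance = d,
                    detached = d > thickness / 2)
  attr(out, "closest") <- t(vapply(hits, `[[`, numeric(3), "closest"))
  out
}

# discrete (Menger) curvature at each interior sample: 4A / (abc)
.discrete_curvature <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(numeric(0))
  p1 <- pts[1:(n - 2L), , drop = FALSE]
  p2 <- pts[2:(n - 1L), , drop = FALSE]
  p3 <- pts[3:n, , drop = FALSE]
  u <- p2 - p1; v <- p3 - p2; w <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  a <- sqrt(rowSums(u^2)); b <- sqrt(rowSums(v^2)); cc <- sqrt(rowSums(w^2))
  area2 <- sqrt(rowSums(cr^2))       # = 2 * triangle area
  ifelse(a * b * cc < 1e-300, 0, 2 * area2 / (a * b * cc))
}

#' Choppiness of a model curve
#'
#' Root-mean-square successive difference of the discrete (Menger) curvature
#' along the model samples. A curve of constant curvature (a genuine helix,
#' a straight line) has choppiness ~0; spline models that wobble in
#' curvature score higher.
#'
#' @param model a \code{\link{build_model}} result (or Hermite baseline).
#' @return Nonnegative scalar (1/\enc{Å}{A}).
#' @export
choppiness <- function(model) {
  pts <- model_samples(model)
  if (nrow(pts) < 3L) stop("need >= 3 samples", call. = FALSE)
  k <- .discrete_curvature(pts)
  if (length(k) < 2L) return(0)
  sqrt(mean(diff(k)^2))
}

#' Cubic Hermite (Catmull-Rom) baseline through guide atoms
#'
#' The spline construction classic visualization pipelines use for helices:
#' a chain of cubic Hermite segments passing exactly through every guide
#' atom, with central-difference tangents. Provided ONLY as the comparison
#' baseline for \code{\link{choppiness}}/\code{\link{detachment}} metrics;
#' it is the approach this package's averaged helical model replaces.
#'
#' @param atoms a \code{\link{helix_trace}} or n x 3 matrix (n >= 2).
#' @param m samples per inter-atom segment.
#' @return A \code{"model_curve"} object (contributors all 1) usable with
#'   the metric functions.
#' @export
hermite_baseline <- function(atoms, m = 16L) {
  if (inherits(atoms, "helix_trace")) atoms <- atoms$xyz
  atoms <- as.matrix(atoms)
  n <- nrow(atoms)
  stopifnot(n >= 2L, m >= 2L)
  tang <- matrix(0, n, 3)
  if (n > 2L)
    tang[2:(n - 1L), ] <- (atoms[3:n, , drop = FALSE] -
                             atoms[1:(n - 2L), , drop = FALSE]) / 2
  tang[1L, ] <- atoms[2L, ] - atoms[1L, ]
  tang[n, ] <- atoms[n, ] - atoms[n - 1L, ]
  u <- seq(0, 1, length.out = m)
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  segments <- lapply(seq_len(n - 1L), function(i)
    outer(h00, atoms[i, ]) + outer(h10, tang[i, ]) +
      outer(h01, atoms[i + 1L, ]) + outer(h11, tang[i + 1L, ]))
  structure(list(segments = segments,
                 contributors = rep(1L, n - 1L), m = m, atoms = atoms,
                 kind = "baseline", chain = "A"),
            class = "model_curve")
}

#' Write a ribbon mesh as OBJ or PLY
#'
#' OBJ: extended \code{v x y z r g b} vertex lines (colors 0-1), \code{vn}
#' normals and \code{f} faces. PLY: ASCII, standard per-vertex uchar colors.
#' Both writers are bit-stable for fixed input.
#'
#' @param mesh a \code{\link{build_ribbon}} result.
#' @param path destination.
#' @return Invisibly, the path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "ribbon_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# helixfit ribbon mesh", con)
  writeLines(sprintf("v %.6f %.6f %.6f %.4f %.4f %.4f",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$colors[, 1] / 255,
                     mesh$colors[, 2] / 255, mesh$colors[, 3] / 255), con)
  writeLines(sprintf("vn %.6f %.6f %.6f", mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$faces[, 1], mesh$faces[, 1],
                     mesh$faces[, 2], mesh$faces[, 2],
                     mesh$faces[, 3], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "ribbon_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               "property uchar red", "property uchar green",
               "property uchar blue",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %.6f %d %d %d",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3],
                     mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3]),
             con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
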