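# End-to-end pipeline: PDB -> traces -> window fits -> scores -> model curve
# -> center polyline -> residue table / JSONL / PDB / mesh outputs, with a
# run manifest. The command-line wrapper in inst/cli/helixfit.R is a thin
# shell over run_pipeline().

#' Pipeline run configuration
#'
#' @param input path to a PDB file.
#' @param mode \code{"protein"} (C-alpha traces, scores computed) or
#'   \code{"dna"} (P traces, parameters and delta only).
#' @param ranges optional path to a segment-range file
#'   (\code{\link{read_segment_ranges}}); fitting is then restricted to
#'   windows fully inside a range.
#' @param fit a \code{\link{fit_config}}.
#' @param score_params_file optional JSON path of score constants; defaults
#'   to the packaged constants.
#' @param stride3 decimate traces by 3 before fitting (DNA mode only).
#' @param samples m samples per inter-atom model segment.
#' @param ribbon_width,ribbon_thickness ribbon geometry (\enc{Å}{A}).
#' @param mesh_format \code{"ply"} or \code{"obj"}.
#' @param outdir output directory (created if missing).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(input, mode = c("protein", "dna"), ranges = NULL,
                       fit = fit_config(), score_params_file = NULL,
                       stride3 = FALSE, samples = 16L, ribbon_width = 2.0,
                       ribbon_thickness = 0.5,
                       mesh_format = c("ply", "obj"), outdir = ".") {
  mode <- match.arg(mode)
  mesh_format <- match.arg(mesh_format)
  if (stride3 && mode == "protein")
    stop("stride3 is a DNA-mode option", call. = FALSE)
  stopifnot(inherits(fit, "fit_config"), samples >= 2L,
            ribbon_width > ribbon_thickness, ribbon_thickness > 0)
  structure(list(input = input, mode = mode, ranges = ranges, fit = fit,
                 score_params_file = score_params_file, stride3 = stride3,
                 samples = as.integer(samples), ribbon_width = ribbon_width,
                 ribbon_thickness = ribbon_thickness,
                 mesh_format = mesh_format, outdir = outdir),
            class = "run_config")
}

# restrict a trace to residues inside the supplied ranges for its chain
.apply_ranges <- function(trace, ranges) {
  rr <- ranges[ranges$chain == trace$chain, , drop = FALSE]
  if (!nrow(rr)) return(NULL)
  keep <- rep(FALSE, length(trace$resno))
  for (k in seq_len(nrow(rr)))
    keep <- keep | (trace$resno >= rr$start[k] & trace$resno <= rr$end[k])
  if (!any(keep)) return(NULL)
  ix <- which(keep)
  helix_trace(trace$xyz[ix, , drop = FALSE], kind = trace$kind,
              chain = trace$chain, resno = trace$resno[ix],
              insert = trace$insert[ix], resid = trace$resid[ix])
}

#' Run the full fitting and export pipeline
#'
#' For every usable trace in the input: fits all quadruple windows, scores
#' them (protein mode), builds the averaged model curve and center polyline,
#' and writes, per trace: the residue table (TSV), fits (JSON lines), the
#' model curve and polyline (JSON + pseudo-atom PDB), the ribbon mesh
#' (OBJ/PLY), and one run manifest (JSON) covering the whole run.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with per-trace results (\code{fit},
#'   \code{scores}, \code{model}, \code{polyline}, \code{files}) and the
#'   manifest. Warnings (short traces, degenerate windows, chain breaks)
#'   are collected in the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  traces <- read_guide_traces(config$input,
                              kind_filter = if (config$mode == "dna")
                                "dna" else "protein")
  ranges <- if (!is.null(config$ranges))
    read_segment_ranges(config$ranges) else NULL
  params <- if (config$mode == "protein") {
    if (!is.null(config$score_params_file))
      read_score_params(config$score_params_file)
    else default_score_params()
  } else NULL
  warnings_log <- character(0)
  if (length(traces) > 1L)
    warnings_log <- c(warnings_log,
                      sprintf("input splits into %d traces (chain breaks or multiple chains)",
                              length(traces)))
  results <- list()
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    if (!is.null(ranges)) {
      tr <- .apply_ranges(tr, ranges)
      if (is.null(tr)) next
    }
    tag <- sprintf("%s_%s%02d", tools::file_path_sans_ext(basename(config$input)),
                   gsub("[^A-Za-z0-9]", "x", tr$chain), ti)
    if (!tr$usable || (config$stride3 && nrow(tr$xyz) < 10L)) {
      warnings_log <- c(warnings_log,
                        sprintf("trace %s too short to fit (%d atoms)",
                                tag, nrow(tr$xyz)))
      fit <- suppressWarnings(helixfit(tr, config$fit,
                                       stride3 = config$stride3,
                                       m = config$samples))
      files <- file.path(config$outdir, paste0(tag, "_residues.tsv"))
      write_residue_table(fit, NULL, files)
      results[[tag]] <- list(fit = fit, files = files)
      next
    }
    fit <- helixfit(tr, config$fit, stride3 = config$stride3,
                    m = config$samples)
    if (nrow(fit$gaps))
      warnings_log <- c(warnings_log,
                        sprintf("trace %s: %d degenerate windows (%s)", tag,
                                nrow(fit$gaps),
                                paste(fit$gaps$window, collapse = ",")))
    scores <- if (config$mode == "protein" && length(good_fits(fit)))
      helix_scores(fit, params) else NULL
    model <- build_model(fit, m = config$samples)
    mesh <- build_ribbon(model, fit, scores, width = config$ribbon_width,
                         thickness = config$ribbon_thickness)
    poly <- if (length(good_fits(fit))) center_polyline(fit) else NULL
    files <- c(
      table = file.path(config$outdir, paste0(tag, "_residues.tsv")),
      fits = file.path(config$outdir, paste0(tag, "_fits.jsonl")),
      model_json = file.path(config$outdir, paste0(tag, "_model.json")),
      model_pdb = file.path(config$outdir, paste0(tag, "_model.pdb")),
      mesh = file.path(config$outdir,
                       paste0(tag, "_ribbon.", config$mesh_format)))
    write_residue_table(fit, scores, files[["table"]])
    write_fits_jsonl(fit, files[["fits"]])
    write_model_json(model, files[["model_json"]])
    write_model_pdb(model, files[["model_pdb"]])
    if (config$mesh_format == "obj") write_obj(mesh, files[["mesh"]])
    else write_ply(mesh, files[["mesh"]])
    if (!is.null(poly)) {
      pj <- file.path(config$outdir, paste0(tag, "_polyline.json"))
      jsonlite::write_json(list(vertices = unname(poly$vertices),
                                bend_angles = poly$bend_angles),
                           pj, digits = NA)
      pp <- file.path(config$outdir, paste0(tag, "_polyline.pdb"))
      write_trace_pdb(poly$vertices, pp, chain = substr(tr$chain, 1, 1),
                      het = TRUE)
      files <- c(files, polyline_json = pj, polyline_pdb = pp)
    }
    results[[tag]] <- list(fit = fit, scores = scores, model = model,
                           polyline = poly, mesh = mesh, files = files)
  }
  manifest <- list(
    package = "helixfit",
    version = as.character(utils::packageVersion("helixfit")),
    config = list(input = config$input, mode = config$mode,
                  ranges = config$ranges,
                  delta_r = config$fit$delta_r, delta_p = config$fit$delta_p,
                  step = config$fit$step, stride3 = config$stride3,
                  samples = config$samples,
                  ribbon_width = config$ribbon_width,
                  ribbon_thickness = config$ribbon_thickness,
                  mesh_format = config$mesh_format),
    traces = names(results),
    warnings = warnings_log)
  mf <- file.path(config$outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(results = results, manifest = manifest,
                 manifest_file = mf))
}
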