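# Reading PDB files into per-chain guide-atom traces (C-alpha for protein,
# P for DNA), segment-range side files, and the per-residue output table.
# PDB parsing itself is delegated to bio3d; altloc resolution, chain-break
# splitting and trace bookkeeping are handled here.

.protein_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL",
                       "MSE", "SEC", "PYL")
.dna_resnames <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")

# maximum consecutive guide-atom distance before a trace is split
.break_threshold <- c(protein_CA = 4.5, dna_P = 8.5)

#' Guide-atom trace of one chain
#'
#' An ordered run of guide atoms (C-alpha or P) from one chain, with residue
#' identifiers and coordinates. Usually produced by
#' \code{\link{read_guide_traces}} or \code{\link{generate_fixture}}; this
#' constructor also accepts a bare n x 3 coordinate matrix.
#'
#' @param xyz n x 3 coordinate matrix (\enc{Å}{A}), file/chain order.
#' @param kind \code{"protein_CA"} or \code{"dna_P"}.
#' @param chain chain identifier.
#' @param resno residue numbers (author numbering, kept verbatim).
#' @param insert insertion codes.
#' @param resid residue names.
#' @return An object of class \code{"helix_trace"}; its \code{usable} field
#'   is TRUE when the trace has at least 4 atoms.
#' @export
helix_trace <- function(xyz, kind = c("protein_CA", "dna_P"), chain = "A",
                        resno = seq_len(nrow(xyz)),
                        insert = rep("", nrow(xyz)),
                        resid = rep(if (kind == "protein_CA") "ALA" else "DA",
                                    nrow(xyz))) {
  kind <- match.arg(kind)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)),
            length(resno) == nrow(xyz), length(insert) == nrow(xyz),
            length(resid) == nrow(xyz))
  structure(list(xyz = xyz, kind = kind, chain = chain,
                 resno = as.integer(resno), insert = as.character(insert),
                 resid = as.character(resid),
                 usable = nrow(xyz) >= 4L),
            class = "helix_trace")
}

#' @export
print.helix_trace <- function(x, ...) {
  cat(sprintf("Guide-atom trace: chain %s, %s, %d atoms (%s)\n",
              x$chain, x$kind, nrow(x$xyz),
              if (x$usable) "usable for fitting" else "too short to fit"))
  invisible(x)
}

# keep one altloc per (chain, resno, insert): highest occupancy,
# ties -> altloc "A", then first seen
.resolve_altloc <- function(df) {
  key <- paste(df$chain, df$resno, df$insert, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                        function(ix) {
                          if (length(ix) == 1L) return(ix)
                          occ <- df$o[ix]
                          occ[is.na(occ)] <- 1
                          ix <- ix[occ == max(occ)]
                          if (length(ix) > 1L && any(df$alt[ix] == "A"))
                            ix <- ix[df$alt[ix] == "A"]
                          ix[1L]
                        }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Read guide-atom traces from a PDB file
#'
#' Extracts one trace per (chain, contiguous run) of guide atoms: C-alpha
#' for amino-acid residues, P for nucleotides. Model 1 is used for
#' multi-model files; alternate locations are resolved to the highest
#' occupancy (ties: altloc "A", then first seen); HETATM records carrying
#' standard residue names are accepted. A trace is split wherever two
#' consecutive guide atoms are farther apart than 4.5 \enc{Å}{A} (protein)
#' or 8.5 \enc{Å}{A} (DNA). Traces shorter than 4 atoms are returned but
#' flagged unusable for fitting.
#'
#' @param pdb_source path to a PDB file.
#' @param kind_filter \code{"protein"}, \code{"dna"} or \code{"both"}.
#' @return List of \code{\link{helix_trace}} objects (possibly empty).
#' @export
read_guide_traces <- function(pdb_source, kind_filter = c("protein", "dna",
                                                          "both")) {
  kind_filter <- match.arg(kind_filter)
  pdb <- tryCatch(bio3d::read.pdb(pdb_source, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("cannot parse PDB file '%s': %s",
                                 pdb_source, conditionMessage(e)),
                         call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop(sprintf("cannot parse PDB file '%s': no atom records", pdb_source),
         call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  out <- list()
  wanted <- list()
  if (kind_filter %in% c("protein", "both"))
    wanted$protein_CA <- at[at$elety == "CA" &
                              at$resid %in% .protein_resnames, , drop = FALSE]
  if (kind_filter %in% c("dna", "both"))
    wanted$dna_P <- at[at$elety == "P" &
                         at$resid %in% .dna_resnames, , drop = FALSE]
  for (kind in names(wanted)) {
    df <- wanted[[kind]]
    if (!nrow(df)) next
    for (ch in unique(df$chain)) {
      sub <- .resolve_altloc(df[df$chain == ch, , drop = FALSE])
      xyz <- as.matrix(sub[, c("x", "y", "z")])
      if (!all(is.finite(xyz))) next
      d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                           xyz[-nrow(xyz), , drop = FALSE])^2))
      run <- cumsum(c(0, d > .break_threshold[[kind]]))
      for (g in unique(run)) {
        ix <- which(run == g)
        out[[length(out) + 1L]] <-
          helix_trace(xyz[ix, , drop = FALSE], kind = kind, chain = ch,
                      resno = sub$resno[ix], insert = sub$insert[ix],
                      resid = sub$resid[ix])
      }
    }
  }
  out
}

#' Read helix segment ranges
#'
#' Parses a plain-text range file, one range per line:
#' \code{chain start end [label]}, whitespace- or comma-delimited. Typically
#' carries externally computed helix assignments (DSSP or PDB HELIX records).
#'
#' @param range_source path to the range file.
#' @return data.frame with columns \code{chain}, \code{start}, \code{end},
#'   \code{label} (empty string when absent).
#' @export
read_segment_ranges <- function(range_source) {
  lines <- readLines(range_source)
  out <- data.frame(chain = character(), start = integer(), end = integer(),
                    label = character())
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[,[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop(sprintf("line %d: expected 'chain start end [label]', got '%s'",
                   i, ln), call. = FALSE)
    start <- suppressWarnings(as.integer(tok[2]))
    end <- suppressWarnings(as.integer(tok[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: non-integer residue bounds in '%s'", i, ln),
           call. = FALSE)
    if (start > end)
      stop(sprintf("line %d: start (%d) > end (%d)", i, start, end),
           call. = FALSE)
    out <- rbind(out, data.frame(chain = tok[1], start = start, end = end,
                                 label = if (length(tok) >= 4L) tok[4] else ""))
  }
  out
}

#' Write the per-residue fit table
#'
#' One row per fitted window start residue: chain, residue, r (\enc{Å}{A}),
#' p (\enc{Å}{A}/residue), t (degrees), delta (\enc{Å}{A}), score, bin
#' label, axis (3 numbers), center (3 numbers). TSV, floats printed with 6
#' decimals; header always present.
#'
#' @param object a \code{\link{helixfit}} object.
#' @param scores optional data.frame from \code{\link{helix_scores}}; when
#'   NULL, score and bin columns are NA (DNA mode).
#' @param path destination.
#' @return Invisibly, the path.
#' @export
write_residue_table <- function(object, scores = NULL, path) {
  stopifnot(inherits(object, "helixfit"))
  header <- c("chain", "residue", "r", "p", "t_deg", "delta", "score", "bin",
              "axis_x", "axis_y", "axis_z", "center_x", "center_y",
              "center_z")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  num <- function(v) sprintf("%.6f", v)
  for (f in good_fits(object)) {
    i <- f$window_start
    res <- object$trace$resno[object$working_index[i]]
    ax <- helix_axis(f$curve)
    sc <- bin <- NA
    if (!is.null(scores)) {
      row <- scores[scores$window == i, , drop = FALSE]
      if (nrow(row)) { sc <- row$h[1]; bin <- as.character(row$bin[1]) }
    }
    writeLines(paste(c(object$trace$chain, res,
                       num(c(f$curve$r, f$curve$p, f$curve$t * 180 / pi,
                             f$delta)),
                       if (is.na(sc)) "NA" else num(sc),
                       if (is.na(bin)) "NA" else bin,
                       num(ax), num(f$curve$origin)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a per-residue fit table back
#'
#' @param path TSV written by \code{\link{write_residue_table}}.
#' @return data.frame with the table's columns, numerics parsed.
#' @export
read_residue_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write a trace (or model samples) as a minimal PDB file
#'
#' Guide atoms are written as ATOM records (CA/P); arbitrary sample points
#' (e.g. model-curve samples) as HETATM pseudo-atoms, loadable in standard
#' viewers.
#'
#' @param xyz n x 3 coordinates, or a \code{\link{helix_trace}}.
#' @param path destination.
#' @param chain chain identifier (single character).
#' @param het write HETATM pseudo-atoms instead of ATOM records.
#' @return Invisibly, the path.
#' @export
write_trace_pdb <- function(xyz, path, chain = "A", het = FALSE) {
  if (inherits(xyz, "helix_trace")) {
    tr <- xyz
    xyz <- tr$xyz
    chain <- substr(tr$chain, 1, 1)
    elety <- if (tr$kind == "protein_CA") "CA" else "P"
    resid <- tr$resid
    resno <- tr$resno
  } else {
    xyz <- as.matrix(xyz)
    elety <- if (het) "C" else "CA"
    resid <- rep(if (het) "MDL" else "ALA", nrow(xyz))
    resno <- seq_len(nrow(xyz))
  }
  rec <- if (het) "HETATM" else "ATOM  "
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            rec, i, sprintf(" %-3s", elety[min(i, length(elety))]),
            resid[min(i, length(resid))], chain,
            resno[min(i, length(resno))] %% 10000L,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
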