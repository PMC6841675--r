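## Stem-cell gating by distance to the central axis, and per-meristem
## min-max normalization of distances and signals.

#' Gate stem cells by distance to the central axis
#'
#' Computes each cell's perpendicular distance to the central axis and
#' flags cells with `dist <= stemCellRadiusFraction * rad_sphere`
#' (boundary inclusive) as stem cells; only those are used in downstream
#' central-zone analyses.
#'
#' @param cells a [NucleusTable-class].
#' @param fit the [SphereFit-class] providing `rad_sphere`.
#' @param axis the central [Axis-class].
#' @param cfg a [ProfileConfig-class] (uses `stemCellRadiusFraction`).
#' @param meristemId label copied into the output records.
#' @param condition genotype/condition label copied into the output.
#' @return A data.frame of cell signal records: `cell_id`, `dist` (um),
#'   one column per channel, `is_stem_cell`, `meristem_id`, `condition`.
#' @export
gateStemCells <- function(cells, fit, axis, cfg = profileConfig(),
                          meristemId = "m1", condition = "wt") {
  stopifnot(is(cells, "NucleusTable"), is(fit, "SphereFit"),
            is(axis, "Axis"))
  if (nCells(cells) == 0L) stop("empty nucleus table")
  dist <- distanceToAxis(cells@coords, axis)
  rec <- data.frame(cell_id = cells@cellId, dist = dist,
                    check.names = FALSE, row.names = NULL)
  if (ncol(cells@intensities))
    rec <- cbind(rec, as.data.frame(cells@intensities))
  rec$is_stem_cell <- dist <= cfg@stemCellRadiusFraction * fit@radius
  rec$meristem_id <- meristemId
  rec$condition <- condition
  rec
}

#' Min-max normalize cell records per meristem
#'
#' Applies `x -> (x - min) / (max - min)` within each meristem,
#' independently to the axis distance and to each signal column, so that
#' signal-versus-distance relationships are comparable across meristems
#' and genotypes. Normalized columns are appended with a `_norm` suffix.
#'
#' @param records data.frame as produced by [gateStemCells()].
#' @param columns columns to normalize (default: `dist` plus every channel
#'   column, i.e. everything numeric except bookkeeping columns).
#' @return The records with `<column>_norm` columns in `[0, 1]` added.
#' @export
minmaxNormalize <- function(records, columns = NULL) {
  if (!nrow(records)) stop("no records to normalize")
  if (is.null(columns)) {
    skip <- c("cell_id", "is_stem_cell", "meristem_id", "condition")
    columns <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                       skip)
  }
  for (cl in columns) {
    out <- rep(NA_real_, nrow(records))
    for (m in unique(records$meristem_id)) {
      sel <- records$meristem_id == m
      x <- records[[cl]][sel]
      rng <- range(x)
      if (diff(rng) == 0)
        stop("degenerate normalization: '", cl, "' is constant within ",
             "meristem '", m, "'")
      out[sel] <- (x - rng[1L]) / diff(rng)
    }
    records[[paste0(cl, "_norm")]] <- out
  }
  records
}
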