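# Plain-text interchange: legacy-ASCII VTK for meshes and surface maps
# (viewable in ParaView), CSV + JSON sidecars for signal traces and lead
# tables.

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Cell data carry the compartment index and conductivity; a JSON sidecar
#' (`<path>.json`) records the label-to-conductivity map.
#'
#' @param mesh a `"thorax_mesh"`.
#' @param path output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "thorax mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(as.character(rep(10L, nt)), con)
  labels <- sort(unique(mesh$label))
  writeLines(c(sprintf("CELL_DATA %d", nt),
               "SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$label, labels) - 1L), con)
  writeLines(c("SCALARS conductivity double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(unname(mesh$conductivity[mesh$label])), con)
  jsonlite::write_json(list(labels = labels,
                            conductivity = as.list(mesh$conductivity)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a surface field map as legacy ASCII VTK
#'
#' Boundary triangulation with point data `phi`, `Ex`, `Ey`, `Ez` and the
#' tangential-field magnitude `Et`.
#'
#' @param field a `"surface_field_map"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surface_vtk <- function(field, path) {
  mesh <- field$mesh
  tri <- mesh$boundary$triangles
  ids <- field$vertex_ids
  remap <- match(tri, ids)
  keep <- rowSums(matrix(is.na(remap), ncol = 3L)) == 0L
  tri2 <- matrix(remap, ncol = 3L)[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface field map", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", length(ids))), con)
  utils::write.table(field$coords, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri2), 4L * nrow(tri2)), con)
  utils::write.table(cbind(3L, tri2 - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("POINT_DATA %d", length(ids)), con)
  wr <- function(nm, v) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(as.character(v), con)
  }
  wr("phi", field$V)
  wr("Ex", field$E[, 1]); wr("Ey", field$E[, 2]); wr("Ez", field$E[, 3])
  wr("Et", sqrt(rowSums(field$tangential^2)))
  invisible(path)
}

#' Write a signal trace as CSV with a JSON sidecar
#'
#' The CSV has columns `time` (s) and `value` (V); the sidecar
#' (`<path>.json`) stores the rate, annotations, motion-event windows and
#' generator provenance.
#'
#' @param trace a `"signal_trace"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  t <- trace$start + (seq_along(trace$samples) - 1L) / trace$rate
  utils::write.csv(data.frame(time = t, value = trace$samples), path,
                   row.names = FALSE)
  side <- list(rate = trace$rate, start = trace$start,
               annotations = trace$annotations,
               provenance = trace$provenance)
  if (!is.null(trace$motion_events)) side$motion_events <- trace$motion_events
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a signal trace written by [write_trace_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist).
#' @return a `"signal_trace"`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- signal_trace(df$value, side$rate,
                     annotations = as.numeric(side$annotations),
                     start = side$start,
                     provenance = as.list(side$provenance))
  if (!is.null(side$motion_events))
    tr$motion_events <- as.data.frame(side$motion_events)
  tr
}
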