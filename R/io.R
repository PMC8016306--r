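# Light IO helpers: JSON study configuration and legacy-VTK export of meshes
# and solved states for external inspection.

#' Read a study configuration from a JSON file
#'
#' Keys mirror the arguments of [study_config()]; missing keys fall back to
#' the defaults.
#'
#' @param path JSON file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  do.call(study_config, raw)
}

#' Export a mesh or solved state as a legacy VTK unstructured grid
#'
#' Writes an ASCII VTK file with the (deformed, when a state is given)
#' quadrilateral mesh, nodal displacements and per-element von Mises stress,
#' strain energy density and volume ratio -- convenient for inspection in
#' ParaView and similar tools.
#'
#' @param model an \code{fe_body} (fingertip, slab or stimulus model).
#' @param path output file path.
#' @param state optional \code{solution_state} solved on the model (or on a
#'   combined system whose first body is the model).
#' @return Invisibly, the path.
#' @export
write_vtk <- function(model, path, state = NULL) {
  nodes <- model$nodes
  n <- nrow(nodes)
  m <- nrow(model$elems)
  u <- matrix(0, n, 2)
  if (!is.null(state)) {
    u <- cbind(state$u[seq(1, 2 * n, by = 2)], state$u[seq(2, 2 * n, by = 2)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("tactillusion mesh export")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  xy <- nodes + u
  writeLines(sprintf("%.8g %.8g 0", xy[, 1], xy[, 2]), con)
  w("CELLS %d %d", m, 5 * m)
  writeLines(sprintf("4 %d %d %d %d", model$elems[, 1] - 1,
                     model$elems[, 2] - 1, model$elems[, 3] - 1,
                     model$elems[, 4] - 1), con)
  w("CELL_TYPES %d", m)
  writeLines(rep("9", m), con) # VTK_QUAD
  w("POINT_DATA %d", n)
  w("VECTORS displacement double")
  writeLines(sprintf("%.8g %.8g 0", u[, 1], u[, 2]), con)
  if (!is.null(state)) {
    f <- state$element_fields[seq_len(m), , drop = FALSE]
    w("CELL_DATA %d", m)
    for (col in c("von_mises", "sed", "J")) {
      w("SCALARS %s double 1", col)
      w("LOOKUP_TABLE default")
      writeLines(sprintf("%.8g", f[, col]), con)
    }
  }
  invisible(path)
}
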