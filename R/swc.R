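#' Morphology container
#'
#' A rooted tree of typed neurite points. Coordinate convention: y increases
#' from white matter toward the pia, x is horizontal within the layer, z is
#' slice depth. Structure codes follow SWC: 1 = soma, 2 = axon, 3 =
#' (basal) dendrite.
#'
#' @param nodes data.frame with columns `id`, `parent` (-1 for the root),
#'   `structure` (integer code), `x`, `y`, `z` (um), `radius` (um).
#' @param cell_id identifier.
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes, cell_id = "cell") {
  req <- c("id", "parent", "structure", "x", "y", "z", "radius")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes <- nodes[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$structure <- as.integer(nodes$structure)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(nodes$radius <= 0)) stop("radii must be > 0")
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0) stop("no root node (parent == -1)")
  if (length(roots) > 1) {
    stop("multiple roots: nodes ", paste(nodes$id[roots], collapse = ", "))
  }
  idx <- match(nodes$parent, nodes$id)
  orphan <- which(nodes$parent != -1L & is.na(idx))
  if (length(orphan)) {
    stop("orphan node(s): ", paste(nodes$id[orphan], collapse = ", "),
         " (parent not present)")
  }
  fwd <- which(nodes$parent != -1L & idx >= seq_len(nrow(nodes)))
  if (length(fwd)) {
    stop("node ", nodes$id[fwd[1]], " appears before its parent")
  }
  structure(list(nodes = nodes, cell_id = as.character(cell_id)),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf(
    "<morphology> %s: %d nodes (%d soma, %d axon, %d dendrite)\n",
    x$cell_id, nrow(nd), sum(nd$structure == 1L), sum(nd$structure == 2L),
    sum(nd$structure == 3L)))
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Standard SWC: `#`-prefixed comments, then 7 whitespace-separated fields per
#' node (`id type x y z radius parent`). Structural errors (orphans, multiple
#' roots, a node preceding its parent) are rejected naming the offending node.
#'
#' @param path path to an `.swc` file.
#' @param cell_id identifier; defaults to the file name.
#' @return A [morphology()].
#' @export
read_swc <- function(path, cell_id = NULL) {
  if (is.null(cell_id)) cell_id <- sub("\\.swc$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no nodes in ", path)
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) != 7L)) {
    stop("SWC line with != 7 fields at data line ",
         which(lengths(parts) != 7L)[1])
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric SWC field in ", path)
  morphology(data.frame(id = m[, 1], structure = m[, 2], x = m[, 3],
                        y = m[, 4], z = m[, 5], radius = m[, 6],
                        parent = m[, 7]),
             cell_id = cell_id)
}

#' Write a morphology to an SWC file
#'
#' @param morph a [morphology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  nd <- morph$nodes
  lines <- c(
    sprintf("# cell_id: %s", morph$cell_id),
    sprintf("%d %d %.6f %.6f %.6f %.6f %d",
            nd$id, nd$structure, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  )
  writeLines(lines, path)
  invisible(path)
}
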