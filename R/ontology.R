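# ---- hierarchical region ontology ----------------------------------------
#
# A rooted region tree in the style of the Allen structure graph: every
# node has an id (> 0; 0 is reserved for "outside atlas / unassigned"), an
# acronym, a parent, a level (root = 1, child level = parent level + 1, at
# most 11 levels), an RGB color, and flags for fiber tracts and ventricles.
# Leaf regions tile the companion atlas label volume.

#' Construct a region ontology
#'
#' @param nodes data.frame with columns id, acronym, name, parent_id (NA for
#'   the root), level, color_hex, is_fiber_tract, is_ventricle.
#' @return An `ontology` object (validated).
#' @export
ontology <- function(nodes) {
  required <- c("id", "acronym", "name", "parent_id", "level", "color_hex",
                "is_fiber_tract", "is_ventricle")
  if (!all(required %in% names(nodes)))
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (any(nodes$id <= 0)) stop("region ids must be > 0 (0 is reserved)")
  if (anyDuplicated(nodes$id)) stop("region ids must be unique")
  roots <- nodes$id[is.na(nodes$parent_id)]
  if (length(roots) != 1) stop("ontology must have exactly one root")
  if (nodes$level[nodes$id == roots] != 1) stop("root must be at level 1")
  if (max(nodes$level) > 11) stop("at most 11 structure levels supported")
  idx <- match(nodes$parent_id, nodes$id)
  has_parent <- !is.na(nodes$parent_id)
  if (any(has_parent & is.na(idx))) stop("parent_id refers to unknown node")
  if (any(nodes$level[has_parent] != nodes$level[idx[has_parent]] + 1))
    stop("every node's level must equal its parent's level + 1")
  # walk up from every node to ensure links form a tree rooted at the root
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); cur <- nodes$id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) stop("parent links contain a cycle")
      seen <- c(seen, cur)
      cur <- nodes$parent_id[match(cur, nodes$id)]
    }
    if (seen[length(seen)] != roots) stop("node not connected to root")
  }
  structure(list(nodes = nodes, root_id = roots), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d regions, levels 1..%d, %d leaves\n",
              nrow(x$nodes), max(x$nodes$level),
              length(ontology_leaves(x))))
  invisible(x)
}

#' Leaf region ids of an ontology
#' @param ont an `ontology`.
#' @return integer vector of ids that have no children.
#' @export
ontology_leaves <- function(ont) {
  setdiff(ont$nodes$id, ont$nodes$parent_id[!is.na(ont$nodes$parent_id)])
}

# effective fiber-tract flag: a node is a fiber tract if it or any ancestor
# carries the flag (the flag propagates to descendants)
ontology_is_fiber <- function(ont, ids) {
  nodes <- ont$nodes
  vapply(ids, function(id) {
    cur <- id
    while (!is.na(cur)) {
      row <- match(cur, nodes$id)
      if (is.na(row)) return(FALSE)
      if (isTRUE(nodes$is_fiber_tract[row])) return(TRUE)
      cur <- nodes$parent_id[row]
    }
    FALSE
  }, logical(1))
}

#' Ancestor of a region at a given level
#'
#' Walks up the tree from `id` until a node at `level` is found. If the
#' node itself sits above (shallower than) the requested level, its own id
#' is returned: a leaf can be coarser than the aggregation level.
#'
#' @param ont an `ontology`.
#' @param ids integer vector of region ids.
#' @param level target structure level.
#' @return integer vector of ancestor ids (or the id itself).
#' @export
ontology_ancestor_at_level <- function(ont, ids, level) {
  nodes <- ont$nodes
  vapply(ids, function(id) {
    row <- match(id, nodes$id)
    if (is.na(row)) return(0L)
    if (nodes$level[row] <= level) return(as.integer(id))
    cur <- id
    while (!is.na(cur)) {
      row <- match(cur, nodes$id)
      if (nodes$level[row] == level) return(as.integer(cur))
      cur <- nodes$parent_id[row]
    }
    as.integer(id)
  }, integer(1))
}

# hex color "#RRGGBB" -> integer RGB triple
hex_to_rgb <- function(hex) {
  m <- grDevices::col2rgb(hex)
  as.integer(m[, 1])
}

#' Write an ontology as structure-graph style JSON
#'
#' Uses the Allen structure-graph field names (id, acronym, name,
#' parent_structure_id, st_level, color_hex_triplet) plus the package's
#' fiber-tract and ventricle flags.
#'
#' @param ont an `ontology`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(ont, path) {
  nodes <- ont$nodes
  out <- data.frame(
    id = nodes$id,
    acronym = nodes$acronym,
    name = nodes$name,
    parent_structure_id = ifelse(is.na(nodes$parent_id), NA, nodes$parent_id),
    st_level = nodes$level,
    color_hex_triplet = sub("^#", "", nodes$color_hex),
    is_fiber_tract = nodes$is_fiber_tract,
    is_ventricle = nodes$is_ventricle,
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read an ontology from structure-graph style JSON
#' @param path JSON file written by [write_ontology_json()] (or any file
#'   with the Allen field names).
#' @return An `ontology`.
#' @export
read_ontology_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- data.frame(
    id = as.integer(raw$id),
    acronym = as.character(raw$acronym),
    name = as.character(raw$name),
    parent_id = suppressWarnings(as.integer(raw$parent_structure_id)),
    level = as.integer(raw$st_level),
    color_hex = paste0("#", raw$color_hex_triplet),
    is_fiber_tract = if (!is.null(raw$is_fiber_tract))
      as.logical(raw$is_fiber_tract) else FALSE,
    is_ventricle = if (!is.null(raw$is_ventricle))
      as.logical(raw$is_ventricle) else FALSE,
    stringsAsFactors = FALSE
  )
  ontology(nodes)
}
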