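# webKnossos-style NML skeleton I/O.
#
# Only the minimal dialect is supported: a <parameters><scale/> element
# giving nm per voxel, <thing> trees with <nodes>/<edges>, and optional
# <comments><comment node=... content=.../> carrying "neck"/"head" region
# labels. Unknown elements are ignored. Node coordinates in the file are
# 0-based voxel indices; they are converted to nm at voxel centers on read.

#' Read spine skeletons from an NML file
#'
#' Each tree in the file becomes one [spine_skeleton()], ordered from its
#' root node (the attachment point, required to be the unique node of degree
#' one at the start of the path) to the tip. Region labels are taken from
#' node comments `"neck"` / `"head"` when present.
#'
#' @param path NML file.
#' @return list with elements `skeletons` (list of [spine_skeleton()]) and
#'   `scale_nm` (numeric length 3).
#' @export
read_skeleton_nml <- function(path) {
  doc <- xml2::read_xml(path)
  sc <- xml2::xml_find_first(doc, ".//parameters/scale")
  if (inherits(sc, "xml_missing"))
    stop("NML file ", path, " has no <parameters><scale> element")
  scale_nm <- as.numeric(c(xml2::xml_attr(sc, "x"), xml2::xml_attr(sc, "y"),
                           xml2::xml_attr(sc, "z")))
  if (any(!is.finite(scale_nm)) || any(scale_nm <= 0))
    stop("NML file ", path, " has an invalid scale element")

  trees <- xml2::xml_find_all(doc, ".//thing")
  skeletons <- lapply(trees, function(tree) {
    tid <- xml2::xml_attr(tree, "id")
    nm <- xml2::xml_attr(tree, "name")
    nodes <- xml2::xml_find_all(tree, ".//nodes/node")
    if (length(nodes) == 0) stop("tree ", tid, " has no nodes in ", path)
    nid <- xml2::xml_attr(nodes, "id")
    vox <- cbind(as.numeric(xml2::xml_attr(nodes, "x")),
                 as.numeric(xml2::xml_attr(nodes, "y")),
                 as.numeric(xml2::xml_attr(nodes, "z")))
    edges <- xml2::xml_find_all(tree, ".//edges/edge")
    src <- xml2::xml_attr(edges, "source")
    tgt <- xml2::xml_attr(edges, "target")
    order_idx <- order_path_nodes(nid, src, tgt, tid, path)
    comments <- xml2::xml_find_all(tree, ".//comments/comment")
    labels <- rep("unlabeled", length(nid))
    if (length(comments) > 0) {
      cn <- xml2::xml_attr(comments, "node")
      cc <- xml2::xml_attr(comments, "content")
      hit <- match(cn, nid)
      ok <- !is.na(hit) & cc %in% c("neck", "head")
      labels[hit[ok]] <- cc[ok]
    }
    meta <- parse_tree_name(nm, tid)
    spine_skeleton(
      nodes = sweep(vox[order_idx, , drop = FALSE], 2, scale_nm, `*`),
      region_labels = labels[order_idx],
      spine_id = meta$spine_id, dendrite_id = meta$dendrite_id,
      neuron_id = meta$neuron_id
    )
  })
  list(skeletons = skeletons, scale_nm = scale_nm)
}

# tree names of the form "neuron/dendrite/spine" carry the hierarchy; plain
# names are used as the spine id
#' @noRd
parse_tree_name <- function(nm, tid) {
  if (is.na(nm) || nm == "") nm <- paste0("tree", tid)
  parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
  if (length(parts) == 3)
    list(neuron_id = parts[1], dendrite_id = parts[2], spine_id = parts[3])
  else
    list(neuron_id = "n1", dendrite_id = "d1", spine_id = nm)
}

# Order node ids along the unique simple path encoded by the edges. The
# root/attachment is the endpoint listed first among degree-1 nodes (we
# require the first node element to be an endpoint so the attachment is the
# written root). Disconnected nodes are an error.
#' @noRd
order_path_nodes <- function(nid, src, tgt, tid, path) {
  n <- length(nid)
  if (n == 1) return(1L)
  if (length(src) != n - 1)
    stop("tree ", tid, " in ", path, " is not a single connected path (",
         n, " nodes, ", length(src), " edges)")
  adj <- vector("list", n)
  names(adj) <- nid
  deg <- stats::setNames(integer(n), nid)
  for (k in seq_along(src)) {
    a <- src[k]; b <- tgt[k]
    if (!(a %in% nid) || !(b %in% nid))
      stop("tree ", tid, " references unknown node in edge ", a, "->", b)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
  }
  if (any(deg == 0))
    stop("tree ", tid, " in ", path, " has orphan nodes: ",
         paste(nid[deg == 0], collapse = ", "))
  ends <- nid[deg == 1]
  if (length(ends) != 2 || any(deg > 2))
    stop("tree ", tid, " in ", path, " is not a simple path")
  root <- if (nid[1] %in% ends) nid[1] else ends[1]
  ord <- character(n)
  ord[1] <- root
  prev <- ""
  for (k in 2:n) {
    nxt <- setdiff(adj[[ord[k - 1]]], prev)
    if (length(nxt) != 1)
      stop("tree ", tid, " in ", path, " is disconnected at node ", ord[k - 1])
    prev <- ord[k - 1]
    ord[k] <- nxt
  }
  match(ord, nid)
}

#' Write spine skeletons to an NML file
#'
#' Inverse of [read_skeleton_nml()]: nm coordinates are divided by the scale
#' to give voxel indices; region labels become node comments; the tree name
#' encodes `neuron/dendrite/spine`.
#'
#' @param skeletons list of [spine_skeleton()].
#' @param scale_nm numeric length-3 nm-per-voxel scale.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skeleton_nml <- function(skeletons, scale_nm, path) {
  stopifnot(length(scale_nm) == 3, all(scale_nm > 0))
  doc <- xml2::xml_new_root("things")
  par <- xml2::xml_add_child(doc, "parameters")
  xml2::xml_add_child(par, "scale",
                      x = format(scale_nm[1], digits = 17),
                      y = format(scale_nm[2], digits = 17),
                      z = format(scale_nm[3], digits = 17))
  for (i in seq_along(skeletons)) {
    sk <- skeletons[[i]]
    tree <- xml2::xml_add_child(
      doc, "thing", id = as.character(i),
      name = paste(sk$neuron_id, sk$dendrite_id, sk$spine_id, sep = "/"))
    nodes <- xml2::xml_add_child(tree, "nodes")
    vox <- sweep(sk$nodes, 2, scale_nm, `/`)
    for (k in seq_len(nrow(vox))) {
      xml2::xml_add_child(nodes, "node", id = as.character(k),
                          x = format(vox[k, 1], digits = 17),
                          y = format(vox[k, 2], digits = 17),
                          z = format(vox[k, 3], digits = 17))
    }
    edges <- xml2::xml_add_child(tree, "edges")
    if (nrow(vox) > 1) {
      for (k in seq_len(nrow(vox) - 1)) {
        xml2::xml_add_child(edges, "edge", source = as.character(k),
                            target = as.character(k + 1))
      }
    }
    lab <- sk$region_labels
    if (any(lab != "unlabeled")) {
      comments <- xml2::xml_add_child(tree, "comments")
      for (k in which(lab != "unlabeled")) {
        xml2::xml_add_child(comments, "comment", node = as.character(k),
                            content = lab[k])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
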