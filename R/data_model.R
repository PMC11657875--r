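#' Construct a spine skeleton
#'
#' A skeleton is the ordered 3D centerline of one spine, from the attachment
#' point on the dendritic shaft (node 1) to the spine tip (last node).
#' Lateral coordinates are in nm; `z` is the imaging-plane position in nm and
#' is quantized to the axial plane pitch (300 nm by default) when the
#' skeleton originates from a stack.
#'
#' @param nodes numeric matrix with columns x, y, z (nm), one row per node,
#'   ordered from attachment to tip.
#' @param region_labels character vector, one of `"neck"`, `"head"`,
#'   `"unlabeled"` per node. Head nodes, if any, must form a contiguous
#'   suffix; neck nodes a contiguous run before them.
#' @param spine_id,dendrite_id,neuron_id identifiers (coerced to character).
#' @return An object of class `spine_skeleton`.
#' @export
spine_skeleton <- function(nodes, region_labels = NULL, spine_id = "s1",
                           dendrite_id = "d1", neuron_id = "n1") {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) stop("skeleton nodes must have columns x, y, z")
  if (nrow(nodes) < 2) stop("skeleton needs >= 2 nodes (spine ", spine_id, ")")
  if (!all(is.finite(nodes))) stop("skeleton coordinates must be finite")
  if (is.null(region_labels)) region_labels <- rep("unlabeled", nrow(nodes))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(nodes))
    stop("one region label per node required (spine ", spine_id, ")")
  bad <- setdiff(unique(region_labels), c("neck", "head", "unlabeled"))
  if (length(bad) > 0) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  check_region_runs(region_labels, spine_id)
  colnames(nodes) <- c("x", "y", "z")
  structure(
    list(nodes = nodes, region_labels = region_labels,
         spine_id = as.character(spine_id),
         dendrite_id = as.character(dendrite_id),
         neuron_id = as.character(neuron_id)),
    class = "spine_skeleton"
  )
}

# head nodes must be a contiguous suffix, neck nodes one contiguous run
# strictly before the head
#' @noRd
check_region_runs <- function(labels, spine_id) {
  head_idx <- which(labels == "head")
  if (length(head_idx) > 0) {
    if (!identical(head_idx, seq(min(head_idx), length(labels))))
      stop("head nodes must form a contiguous suffix (spine ", spine_id, ")")
  }
  neck_idx <- which(labels == "neck")
  if (length(neck_idx) > 0) {
    if (!identical(neck_idx, seq(min(neck_idx), max(neck_idx))))
      stop("neck nodes must be contiguous (spine ", spine_id, ")")
    if (length(head_idx) > 0 && max(neck_idx) > min(head_idx))
      stop("neck nodes must precede head nodes (spine ", spine_id, ")")
  }
  invisible(TRUE)
}

#' Construct a per-plane segmentation outline
#'
#' The spine's manually drawn outline in one imaging plane: a simple polygon
#' around the centerline in that plane.
#'
#' @param z plane position, nm.
#' @param vertices numeric matrix with columns x, y (nm), ordered, no
#'   repeated closing vertex.
#' @return An object of class `plane_outline`.
#' @export
plane_outline <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2) stop("outline vertices must have columns x, y")
  if (nrow(vertices) < 3) stop("outline needs >= 3 vertices")
  if (!all(is.finite(vertices))) stop("outline vertices must be finite")
  if (!polygon_is_simple(vertices))
    stop("outline polygon at z = ", z, " is self-intersecting")
  colnames(vertices) <- c("x", "y")
  structure(list(z = as.numeric(z), vertices = vertices),
            class = "plane_outline")
}

#' Construct a spine annotation
#'
#' One spine's skeleton plus its per-plane outlines. Spines with
#' `complete = FALSE` (morphology not clearly recognizable) are carried
#' through I/O but excluded from morphometry.
#'
#' @param skeleton a [spine_skeleton()].
#' @param outlines list of [plane_outline()]s, one per imaging plane touched
#'   by the skeleton.
#' @param complete logical; include in morphometry?
#' @param notes named list of free-form flags (e.g. ground-truth class,
#'   spinule flag).
#' @param z_tol tolerance (nm) for matching outline planes to node planes.
#' @return An object of class `spine_annotation`.
#' @export
spine_annotation <- function(skeleton, outlines, complete = TRUE,
                             notes = list(), z_tol = 1e-6) {
  stopifnot(inherits(skeleton, "spine_skeleton"))
  if (!is.list(outlines) || !all(vapply(outlines, inherits, TRUE, "plane_outline")))
    stop("outlines must be a list of plane_outline objects")
  node_z <- skeleton$nodes[, "z"]
  for (o in outlines) {
    if (!any(abs(node_z - o$z) <= z_tol))
      stop("outline plane z = ", o$z, " has no skeleton node (spine ",
           skeleton$spine_id, ")")
  }
  structure(list(skeleton = skeleton, outlines = outlines,
                 complete = isTRUE(complete), notes = notes),
            class = "spine_annotation")
}

#' Construct a neuron dataset
#'
#' The neuron -> dendrite -> spine hierarchy plus acquisition metadata.
#'
#' @param spines list of [spine_annotation()]s; hierarchy is read from the
#'   `neuron_id` / `dendrite_id` fields of each skeleton.
#' @param scale_nm numeric length-3 voxel pitch (x, y, z) in nm.
#' @param metadata named list (animal id, labeling method, generator seed...).
#' @return An object of class `neuron_dataset`.
#' @export
neuron_dataset <- function(spines, scale_nm = c(20, 20, 300),
                           metadata = list()) {
  if (!is.list(spines) || !all(vapply(spines, inherits, TRUE, "spine_annotation")))
    stop("spines must be a list of spine_annotation objects")
  ids <- vapply(spines, function(s) s$skeleton$spine_id, "")
  if (anyDuplicated(ids))
    stop("duplicate spine ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stopifnot(length(scale_nm) == 3, all(scale_nm > 0))
  structure(list(spines = spines, scale_nm = as.numeric(scale_nm),
                 metadata = metadata),
            class = "neuron_dataset")
}

#' Per-spine id table of a dataset
#'
#' @param dataset a [neuron_dataset()].
#' @return data.frame with columns neuron_id, dendrite_id, spine_id,
#'   complete, true_class (NA when the spine carries no ground truth),
#'   ordered by (neuron, dendrite, spine).
#' @export
dataset_index <- function(dataset) {
  stopifnot(inherits(dataset, "neuron_dataset"))
  df <- do.call(rbind, lapply(dataset$spines, function(s) {
    tc <- s$notes$true_class
    data.frame(
      neuron_id = s$skeleton$neuron_id,
      dendrite_id = s$skeleton$dendrite_id,
      spine_id = s$skeleton$spine_id,
      complete = s$complete,
      true_class = if (is.null(tc)) NA_integer_ else as.integer(tc),
      stringsAsFactors = FALSE
    )
  }))
  df[order(df$neuron_id, df$dendrite_id, df$spine_id), , drop = FALSE]
}

#' @export
print.spine_skeleton <- function(x, ...) {
  cat("<spine_skeleton>", x$spine_id, "-", nrow(x$nodes), "nodes,",
      "dendrite", x$dendrite_id, "neuron", x$neuron_id, "\n")
  invisible(x)
}

#' @export
print.neuron_dataset <- function(x, ...) {
  idx <- dataset_index(x)
  cat("<neuron_dataset>", length(x$spines), "spines,",
      length(unique(idx$dendrite_id)), "dendrites,",
      length(unique(idx$neuron_id)), "neurons;",
      sum(!idx$complete), "incomplete\n")
  invisible(x)
}
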