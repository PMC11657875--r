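# Annotation JSON schema:
# {
#   "scale_nm": [20, 20, 300],
#   "metadata": {...},
#   "neurons": [{
#     "id": "n1",
#     "dendrites": [{
#       "id": "d1",
#       "spines": [{
#         "id": "s1", "complete": true,
#         "nodes": [[x, y, z], ...],            # nm
#         "region_labels": ["unlabeled", ...],  # one per node
#         "outlines": [{"z": z, "vertices": [[x, y], ...]}, ...],
#         "notes": {...}                        # optional
#       }]
#     }]
#   }]
# }
# Unlike NML, JSON node coordinates are physical nm; scale_nm is metadata.

#' Read a neuron dataset from annotation JSON
#'
#' Fully validates the hierarchy: outline planes must contain a skeleton
#' node, polygons must be simple, spine ids unique. Violations are rejected
#' with the offending spine id. `complete = false` spines are loaded but
#' flagged for exclusion from morphometry.
#'
#' @param path JSON file.
#' @return a [neuron_dataset()].
#' @export
read_annotations_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$neurons)) stop("annotation JSON ", path, " has no 'neurons'")
  scale_nm <- if (is.null(j$scale_nm)) c(20, 20, 300) else
    as.numeric(unlist(j$scale_nm))
  spines <- list()
  for (nn in j$neurons) {
    for (dd in nn$dendrites) {
      for (sp in dd$spines) {
        nodes <- do.call(rbind, lapply(sp$nodes, function(p) as.numeric(unlist(p))))
        labels <- if (is.null(sp$region_labels)) NULL else
          as.character(unlist(sp$region_labels))
        sk <- spine_skeleton(nodes, labels, spine_id = sp$id,
                             dendrite_id = dd$id, neuron_id = nn$id)
        outlines <- lapply(sp$outlines, function(o) {
          plane_outline(as.numeric(o$z),
                        do.call(rbind, lapply(o$vertices,
                                              function(v) as.numeric(unlist(v)))))
        })
        notes <- if (is.null(sp$notes)) list() else
          lapply(sp$notes, function(x) if (is.list(x)) unlist(x) else x)
        spines[[length(spines) + 1]] <- spine_annotation(
          sk, outlines, complete = isTRUE(sp$complete), notes = notes)
      }
    }
  }
  metadata <- if (is.null(j$metadata)) list() else j$metadata
  neuron_dataset(spines, scale_nm = scale_nm, metadata = metadata)
}

#' Write a neuron dataset to annotation JSON
#'
#' @param dataset a [neuron_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "neuron_dataset"))
  idx <- dataset_index(dataset)
  by_spine <- stats::setNames(dataset$spines,
                              vapply(dataset$spines,
                                     function(s) s$skeleton$spine_id, ""))
  neurons <- lapply(split(idx, idx$neuron_id), function(nidx) {
    dendrites <- lapply(split(nidx, nidx$dendrite_id), function(didx) {
      spines <- lapply(didx$spine_id, function(sid) {
        s <- by_spine[[sid]]
        list(
          id = s$skeleton$spine_id,
          complete = s$complete,
          nodes = unname(apply(s$skeleton$nodes, 1, as.list, simplify = FALSE)),
          region_labels = as.list(s$skeleton$region_labels),
          outlines = lapply(s$outlines, function(o) list(
            z = o$z,
            vertices = unname(apply(o$vertices, 1, as.list, simplify = FALSE))
          )),
          notes = s$notes
        )
      })
      list(id = didx$dendrite_id[1], spines = spines)
    })
    list(id = nidx$neuron_id[1], dendrites = unname(dendrites))
  })
  out <- list(scale_nm = dataset$scale_nm, metadata = dataset$metadata,
              neurons = unname(neurons))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}
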