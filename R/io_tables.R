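#' Write the result tables of a pipeline run
#'
#' Emits deterministic CSV files: per-spine descriptors with class labels,
#' the dendrite x class count table, and the statistical test results. Rows
#' are ordered by (neuron, dendrite, spine id) so re-running on identical
#' input gives byte-identical files.
#'
#' @param dataset a [neuron_dataset()].
#' @param descriptors data.frame from [descriptor_table()] keyed by spine_id.
#' @param labels named integer vector of class labels keyed by spine_id.
#' @param stats data.frame of test results (may have zero rows), with columns
#'   test, comparison, statistic, df, p, p_adjusted.
#' @param out_dir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
write_results_tables <- function(dataset, descriptors, labels, stats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- dataset_index(dataset)
  idx <- idx[idx$spine_id %in% names(labels), , drop = FALSE]
  if (!setequal(idx$spine_id, names(labels)) ||
      !all(descriptors$spine_id %in% idx$spine_id) ||
      !setequal(descriptors$spine_id, names(labels)))
    stop("spine id mismatch between dataset, descriptors and labels")

  desc <- merge(idx[, c("neuron_id", "dendrite_id", "spine_id")], descriptors,
                by = "spine_id", sort = FALSE)
  desc$class <- unname(labels[desc$spine_id])
  desc <- desc[order(desc$neuron_id, desc$dendrite_id, desc$spine_id), ]
  desc <- desc[, c("neuron_id", "dendrite_id", "spine_id",
                   setdiff(names(descriptors), "spine_id"), "class")]

  counts <- class_count_table(idx, labels)$counts
  counts_df <- data.frame(dendrite_id = rownames(counts),
                          as.data.frame(unclass(counts)),
                          check.names = FALSE)

  if (is.null(stats) || nrow(stats) == 0) {
    stats <- data.frame(test = character(), comparison = character(),
                        statistic = numeric(), df = numeric(),
                        p = numeric(), p_adjusted = numeric())
  }

  files <- c(descriptors = file.path(out_dir, "spine_descriptors.csv"),
             class_counts = file.path(out_dir, "class_counts.csv"),
             stats = file.path(out_dir, "test_results.csv"))
  utils::write.csv(desc, files["descriptors"], row.names = FALSE)
  utils::write.csv(counts_df, files["class_counts"], row.names = FALSE)
  utils::write.csv(stats, files["stats"], row.names = FALSE)
  invisible(files)
}

#' Write a width-profile table in long format
#'
#' @param profiles list of width profiles (see [compute_width_profile()]).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  long <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(spine_id = p$spine_id, s = p$s, d = p$d, region = p$region,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$spine_id, long$s), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format width-profile table
#'
#' @param path CSV written by [write_profiles_csv()].
#' @return named list of width profiles.
#' @export
read_profiles_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$spine_id), function(g) {
    g <- g[order(g$s), ]
    structure(list(s = g$s, d = g$d, region = g$region,
                   spine_id = g$spine_id[1]),
              class = "width_profile")
  })
}
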