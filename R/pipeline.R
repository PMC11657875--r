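# Pipeline orchestration: simulate -> (deconvolve) -> measure -> cluster ->
# compare, with a manifest and deterministic outputs, plus a small
# subcommand-style command line interface.

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. The on-disk dialect is JSON
#' (read with [read_pipeline_config()]); command-line flags override file
#' values.
#'
#' @param input annotation JSON path, or `NULL` to simulate.
#' @param out_dir run directory for all outputs.
#' @param seed integer seed for every random stage.
#' @param scale_nm voxel pitch (x, y, z) nm.
#' @param step_nm width-profile sampling step, nm (default 20).
#' @param n_profile resampled profile points (default 100).
#' @param length_repeats repeated length dimensions (default 75).
#' @param k_range candidate class counts for Davies-Bouldin selection.
#' @param alpha significance level.
#' @param shuffles shuffle-control iterations (0 disables).
#' @param simulate list of generator settings (`dendrites` data.frame,
#'   optional `noise_cv`), or `NULL` when `input` is given.
#' @param deconvolve logical; run the Wiener stage on a rendered stack
#'   (requires simulation; annotation-only inputs skip it).
#' @param fwhm_nm,reg PSF width and Wiener regularization for the
#'   deconvolution stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out_dir = "run", seed = 1,
                            scale_nm = c(20, 20, 300), step_nm = 20,
                            n_profile = 100, length_repeats = 75,
                            k_range = 2:8, alpha = 0.05, shuffles = 0,
                            simulate = NULL, deconvolve = FALSE,
                            fwhm_nm = 50, reg = 1e-2) {
  stopifnot(step_nm > 0, n_profile > 0, length_repeats > 0, alpha > 0,
            shuffles >= 0, fwhm_nm > 0, reg >= 0, all(scale_nm > 0))
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 scale_nm = scale_nm, step_nm = step_nm,
                 n_profile = n_profile, length_repeats = length_repeats,
                 k_range = k_range, alpha = alpha, shuffles = shuffles,
                 simulate = simulate, deconvolve = deconvolve,
                 fwhm_nm = fwhm_nm, reg = reg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat JSON file
#' @param path JSON file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$simulate) && !is.null(j$simulate$dendrites))
    j$simulate$dendrites <- as.data.frame(j$simulate$dendrites)
  do.call(pipeline_config, j)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load annotations), optional plane-wise Wiener
#' deconvolution of a rendered stack, width-profile measurement and
#' descriptors, clustering with Davies-Bouldin class-number selection, and
#' the heterogeneity statistics (plus shuffle control when configured).
#' All outputs and a manifest (seed, config, stage counts, config hash) are
#' written under `config$out_dir`; a second run on identical input produces
#' identical tables.
#'
#' @param config a [pipeline_config()].
#' @return list with `dataset`, `measurement`, `model`, `tests`, `shuffle`,
#'   `manifest`, and the output `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "spinemorph",
                   version = as.character(utils::packageVersion("spinemorph")),
                   seed = config$seed, stages = character(0))

  # --- stage: input -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- synth_config(dendrites = as.data.frame(sim$dendrites),
                        seed = config$seed, scale_nm = config$scale_nm,
                        noise_cv = sim$noise_cv)
    dataset <- sample_dataset(cfg)
    write_annotations_json(dataset,
                           file.path(config$out_dir, "annotations.json"))
    manifest$stages <- c(manifest$stages, "simulate")
  } else {
    if (is.null(config$input) || !file.exists(config$input))
      stop("stage input: annotation file not found: ", config$input)
    dataset <- read_annotations_json(config$input)
    manifest$stages <- c(manifest$stages, "load")
  }
  idx <- dataset_index(dataset)
  manifest$n_spines <- nrow(idx)
  manifest$n_excluded <- sum(!idx$complete)
  message("stage input: ", nrow(idx), " spines, ", sum(!idx$complete),
          " excluded (incomplete)")

  # --- stage: deconvolve (optional, simulated stacks only) ---------------
  if (isTRUE(config$deconvolve)) {
    rend <- render_stack(dataset, psf_fwhm = config$fwhm_nm,
                         photon_scale = Inf,
                         pixel_nm = config$scale_nm[1])
    psf <- lorentzian_psf(config$fwhm_nm, config$scale_nm[1])
    dec <- deconvolve_stack(rend$stack, psf, config$reg)
    write_stack_txt(dec, file.path(config$out_dir, "deconvolved_stack.txt"))
    manifest$stages <- c(manifest$stages, "deconvolve")
    message("stage deconvolve: ", dim(dec)[3], " planes")
  }

  # --- stage: measure -----------------------------------------------------
  meas <- measure_dataset(dataset, step_nm = config$step_nm)
  write_profiles_csv(meas$profiles,
                     file.path(config$out_dir, "width_profiles.csv"))
  manifest$stages <- c(manifest$stages, "measure")
  manifest$n_measured <- length(meas$profiles)
  message("stage measure: ", length(meas$profiles), " profiles")

  # --- stage: cluster -----------------------------------------------------
  model <- cluster_spines(meas$profiles, k_range = config$k_range)
  manifest$stages <- c(manifest$stages, "cluster")
  manifest$k_selected <- model$k
  message("stage cluster: k = ", model$k)

  # --- stage: compare -----------------------------------------------------
  tests <- heterogeneity_tests(idx[idx$complete, , drop = FALSE],
                               model$labels, meas$descriptors,
                               alpha = config$alpha)
  shuffle <- NULL
  if (config$shuffles > 0) {
    shuffle <- shuffle_control(idx[idx$complete, ], model$labels,
                               n_shuffles = config$shuffles,
                               alpha = config$alpha,
                               seed = config$seed + 1L)
  }
  manifest$stages <- c(manifest$stages, "compare")

  stat_rows <- rbind(
    tests$omnibus[, c("test", "comparison", "statistic", "df", "p",
                      "p_adjusted")],
    if (!is.null(tests$per_neuron))
      tests$per_neuron[, c("test", "comparison", "statistic", "df", "p",
                           "p_adjusted")],
    if (!is.null(tests$pairwise_all))
      tests$pairwise_all[, c("test", "comparison", "statistic", "df", "p",
                             "p_adjusted")],
    if (!is.null(tests$kruskal))
      tests$kruskal[, c("test", "comparison", "statistic", "df", "p",
                        "p_adjusted")]
  )
  files <- write_results_tables(dataset, meas$descriptors, model$labels,
                                stat_rows, config$out_dir)

  # config hash over the canonical JSON of the configuration
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, config = tmp, manifest = manifest_path)

  list(dataset = dataset, measurement = meas, model = model, tests = tests,
       shuffle = shuffle, manifest = manifest, files = files)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `deconvolve`, `measure`, `cluster`, `compare`,
#' `run`. Flags are `--key value` pairs; `--config file.json` supplies a
#' [read_pipeline_config()] file whose values individual flags override.
#' Installed as the `spinemorph` script under `exec/`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0 invisibly (errors propagate).
#' @export
spinemorph_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: spinemorph <simulate|deconvolve|measure|cluster|compare|run> [--key value ...]")
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.null(opts$input)) cfg$input <- opts$input

  switch(cmd,
    simulate = {
      dend <- data.frame(neuron_id = "n1", dendrite_id = c("d1", "d2"),
                         n_spines = as.integer(num(opts$n, 50)),
                         p1 = 0.25, p2 = 0.25, p3 = 0.25, p4 = 0.25)
      ds <- sample_dataset(synth_config(dend, seed = cfg$seed))
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_annotations_json(ds, file.path(cfg$out_dir, "annotations.json"))
      gt <- dataset_index(ds)
      utils::write.csv(gt, file.path(cfg$out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    },
    deconvolve = {
      stack <- read_stack_txt(opts$input)
      psf <- lorentzian_psf(num(opts$fwhm, 50), num(opts$pixel, 20))
      out <- deconvolve_stack(stack, psf, num(opts$reg, 1e-2))
      write_stack_txt(out, opts$out)
    },
    measure = {
      ds <- read_annotations_json(cfg$input)
      meas <- measure_dataset(ds, step_nm = num(opts$step, cfg$step_nm))
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_profiles_csv(meas$profiles,
                         file.path(cfg$out_dir, "width_profiles.csv"))
      utils::write.csv(meas$descriptors,
                       file.path(cfg$out_dir, "descriptors.csv"),
                       row.names = FALSE)
    },
    cluster = {
      profiles <- read_profiles_csv(opts$input)
      kmin <- as.integer(num(opts$kmin, 2))
      kmax <- as.integer(num(opts$kmax, 8))
      model <- cluster_spines(profiles, k_range = kmin:kmax)
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(data.frame(spine_id = names(model$labels),
                                  class = unname(model$labels)),
                       file.path(cfg$out_dir, "labels.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(k = as.integer(names(model$db_curve)),
                                  db = unname(model$db_curve)),
                       file.path(cfg$out_dir, "db_curve.csv"),
                       row.names = FALSE)
      cmp <- class_mean_profiles(profiles, labels = model$labels[
        vapply(profiles, function(p) p$spine_id, "")])
      prof_df <- do.call(rbind, lapply(cmp, function(cl)
        data.frame(class = cl$class, idx = 1:100,
                   s = seq(0, cl$mean_length, length.out = 100),
                   d = cl$mean_profile)))
      utils::write.csv(prof_df, file.path(cfg$out_dir, "class_profiles.csv"),
                       row.names = FALSE)
    },
    compare = {
      ds <- read_annotations_json(cfg$input)
      labels_df <- utils::read.csv(opts$labels)
      labels <- stats::setNames(labels_df$class, labels_df$spine_id)
      idx <- dataset_index(ds)
      tests <- heterogeneity_tests(idx, labels, alpha = num(opts$alpha, 0.05))
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rbind(tests$omnibus[1:6], tests$per_neuron[1:6]),
                       file.path(cfg$out_dir, "omnibus.csv"),
                       row.names = FALSE)
      utils::write.csv(tests$pairwise_all,
                       file.path(cfg$out_dir, "pairwise.csv"),
                       row.names = FALSE)
      n_sh <- as.integer(num(opts$shuffles, 0))
      if (n_sh > 0) {
        sh <- shuffle_control(idx[idx$complete, ], labels,
                              n_shuffles = n_sh,
                              alpha = num(opts$alpha, 0.05),
                              seed = cfg$seed)
        utils::write.csv(data.frame(shuffle = seq_along(sh$chi_square_p),
                                    p = sh$chi_square_p),
                         file.path(cfg$out_dir, "shuffle_summary.csv"),
                         row.names = FALSE)
      }
    },
    run = {
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

#' @noRd
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --flag, got ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}
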