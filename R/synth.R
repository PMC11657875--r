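# Synthetic spine generator.
#
# Stands in for the (unreleased) microscope data: spines of four
# morphological classes with known ground truth, dendrites carrying
# controllable class mixtures, and optional rendered image stacks. The
# four class templates are package constants chosen to reproduce the
# qualitative shapes of the published class-average width profiles:
# stubby-like (short, wide, but with a resolvable neck), mushroom-like
# (large head over a narrow neck), thin (long narrow neck, small head), and
# filopodia-like (long, near-uniform, monotonically tapering, no head
# swelling). Super-resolution data resolve a neck even on the shortest
# spines, so every template except the filopodia-like one has a width
# minimum strictly below both flanking maxima.

#' The four class archetypes
#'
#' Each archetype holds a 100-point diameter template (nm) on the normalized
#' arc coordinate `[0, 1]` (0 = dendrite attachment, 1 = tip), a length
#' distribution, a default multiplicative diameter noise level, and the
#' neck/head arc spans used to set region labels on generated skeletons.
#'
#' Template shapes (sums of Gaussian bumps over a baseline) and length
#' scales are deterministic package constants; lengths are in the
#' 0.5-3 um range typical of cortical spines.
#'
#' @return list of 4 `class_archetype` objects with fields `class_id`,
#'   `name`, `template` (100 diameters, nm), `length_mean`, `length_sd`
#'   (nm), `diameter_noise_cv`, `neck_span`, `head_span` (arc fractions).
#' @export
default_archetypes <- function() {
  t <- seq(0, 1, length.out = 100)
  bump <- function(c, w, h) h * exp(-((t - c) / w)^2)
  arch <- function(class_id, name, template, length_mean, length_sd,
                   neck_span, head_span) {
    stopifnot(all(template > 0))
    structure(list(class_id = class_id, name = name, template = template,
                   length_mean = length_mean, length_sd = length_sd,
                   diameter_noise_cv = 0.10,
                   neck_span = neck_span, head_span = head_span),
              class = "class_archetype")
  }
  list(
    arch(1L, "stubby-like",
         210 + bump(0, 0.25, 90) + bump(0.72, 0.18, 170),
         length_mean = 700, length_sd = 100,
         neck_span = c(0.15, 0.50), head_span = c(0.50, 1)),
    arch(2L, "mushroom-like",
         140 + bump(0, 0.16, 160) + bump(0.78, 0.13, 420),
         length_mean = 1150, length_sd = 150,
         neck_span = c(0.20, 0.55), head_span = c(0.55, 1)),
    arch(3L, "thin",
         110 + bump(0, 0.13, 140) + bump(0.85, 0.10, 130),
         length_mean = 1700, length_sd = 250,
         neck_span = c(0.18, 0.65), head_span = c(0.72, 1)),
    arch(4L, "filopodia-like",
         90 + 170 * (1 - t)^1.5,
         length_mean = 2600, length_sd = 400,
         neck_span = c(0.10, 0.85), head_span = c(0.85, 1))
  )
}

# template diameter at arc fractions tt (linear interpolation on the
# 100-point grid)
#' @noRd
template_at <- function(template, tt) {
  stats::approx(seq(0, 1, length.out = length(template)), template,
                xout = pmin(pmax(tt, 0), 1), rule = 2)$y
}

#' Sample one synthetic spine
#'
#' Draws a spine length from the archetype's (truncated > 200 nm) normal
#' length distribution, perturbs the diameter template multiplicatively with
#' lognormal noise of the requested coefficient of variation, builds a
#' gently bending 3D skeleton spanning one or more imaging planes (axial
#' pitch `scale_nm[3]`), and constructs per-plane ribbon outlines whose
#' local width equals the (noisy) target diameter. Uses the current R RNG
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param archetype a `class_archetype` from [default_archetypes()].
#' @param spine_id,dendrite_id,neuron_id identifiers.
#' @param scale_nm voxel pitch (x, y, z), nm.
#' @param noise_cv diameter noise CV; `NULL` uses the archetype default.
#' @param bend_sd in-plane heading change per step, radians (0 = straight).
#' @param step_nm skeleton node spacing along the path, nm.
#' @param straight logical; force a straight, single-plane skeleton
#'   (used for generator/measurer consistency checks).
#' @param origin numeric length-3 attachment position, nm.
#' @return a [spine_annotation()] with the ground-truth class in
#'   `notes$true_class`.
#' @export
sample_spine <- function(archetype, spine_id = "s1", dendrite_id = "d1",
                         neuron_id = "n1", scale_nm = c(20, 20, 300),
                         noise_cv = NULL, bend_sd = 0.05, step_nm = 50,
                         straight = FALSE, origin = c(0, 0, 0)) {
  stopifnot(inherits(archetype, "class_archetype"))
  pitch <- scale_nm[3]
  if (is.null(noise_cv)) noise_cv <- archetype$diameter_noise_cv

  # truncated-normal length draw
  repeat {
    len <- stats::rnorm(1, archetype$length_mean, archetype$length_sd)
    if (len > 200) break
  }

  # multiplicative lognormal noise on the 100 template points, mean 1
  template <- archetype$template
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    template <- template * exp(stats::rnorm(100, 0, sigma) - sigma^2 / 2)
  }

  phi0 <- if (straight) 0 else stats::runif(1, 0, 2 * pi)
  n_jumps <- if (straight) 0L else {
    max_jumps <- max(0L, floor(len / 900))
    if (max_jumps == 0) 0L else sample.int(max_jumps + 1L, 1L) - 1L
  }
  bend <- if (straight) 0 else bend_sd

  # geometry can in principle self-intersect for extreme bends; halve the
  # bend and retry (deterministic under the seeded stream)
  for (attempt in 1:5) {
    ann <- try(build_spine_geometry(
      template, len, archetype, n_jumps, phi0, bend / attempt, step_nm,
      pitch, origin, spine_id, dendrite_id, neuron_id), silent = TRUE)
    if (!inherits(ann, "try-error")) return(ann)
  }
  stop(ann)
}

#' @noRd
build_spine_geometry <- function(template, len, archetype, n_jumps, phi0,
                                 bend_sd, step_nm, pitch, origin,
                                 spine_id, dendrite_id, neuron_id) {
  jump_len <- sqrt(step_nm^2 + pitch^2)
  if (len - n_jumps * jump_len < 4 * step_nm)
    n_jumps <- max(0L, floor((len - 4 * step_nm) / jump_len))
  flat_len <- len - n_jumps * jump_len
  n_runs <- n_jumps + 1L
  # >= 2 flat steps per plane run so every plane has >= 3 in-plane nodes
  n_flat <- max(2L * n_runs, ceiling(flat_len / step_nm))
  flat_step <- flat_len / n_flat

  # distribute flat steps over runs as evenly as possible
  per_run <- rep(n_flat %/% n_runs, n_runs)
  extra <- n_flat %% n_runs
  if (extra > 0) per_run[seq_len(extra)] <- per_run[seq_len(extra)] + 1L

  # segment plan: 3D length and dz per segment
  seg_len <- numeric(0); seg_dz <- numeric(0)
  for (r in seq_len(n_runs)) {
    seg_len <- c(seg_len, rep(flat_step, per_run[r]))
    seg_dz <- c(seg_dz, rep(0, per_run[r]))
    if (r < n_runs) {
      seg_len <- c(seg_len, jump_len)
      seg_dz <- c(seg_dz, pitch)
    }
  }

  n_seg <- length(seg_len)
  phi <- phi0
  pos <- matrix(0, n_seg + 1, 3)
  pos[1, ] <- origin
  for (k in seq_len(n_seg)) {
    if (seg_dz[k] == 0) {
      phi <- phi + stats::rnorm(1, 0, bend_sd)
      step_xy <- seg_len[k]
    } else {
      step_xy <- step_nm
    }
    pos[k + 1, ] <- pos[k, ] +
      c(step_xy * cos(phi), step_xy * sin(phi), seg_dz[k])
  }

  s_nodes <- c(0, cumsum(seg_len))
  t_nodes <- s_nodes / len
  labels <- rep("unlabeled", n_seg + 1)
  labels[t_nodes >= archetype$neck_span[1] &
           t_nodes <= archetype$neck_span[2]] <- "neck"
  labels[t_nodes >= archetype$head_span[1]] <- "head"

  skeleton <- spine_skeleton(pos, labels, spine_id, dendrite_id, neuron_id)
  outlines <- ribbon_outlines(pos, s_nodes / len, template, cap_ext = 30)
  spine_annotation(skeleton, outlines, complete = TRUE,
                   notes = list(true_class = archetype$class_id,
                                true_length = len))
}

# Build one ribbon polygon per imaging plane: offset the in-plane node run
# by half the local target diameter on both sides of the local tangent, and
# extend the run ends slightly so skeleton endpoints lie strictly inside.
#' @noRd
ribbon_outlines <- function(pos, t_nodes, template, cap_ext = 30) {
  zs <- pos[, 3]
  runs <- split(seq_len(nrow(pos)), cumsum(c(1, diff(zs) != 0)))
  runs <- runs[vapply(runs, length, 1L) >= 2]
  lapply(unname(runs), function(idx) {
    p <- pos[idx, 1:2, drop = FALSE]
    d <- template_at(template, t_nodes[idx])
    m <- nrow(p)
    # tangents: central differences, one-sided at the ends
    tx <- numeric(m); ty <- numeric(m)
    tx[1] <- p[2, 1] - p[1, 1]; ty[1] <- p[2, 2] - p[1, 2]
    tx[m] <- p[m, 1] - p[m - 1, 1]; ty[m] <- p[m, 2] - p[m - 1, 2]
    if (m > 2) {
      tx[2:(m - 1)] <- p[3:m, 1] - p[1:(m - 2), 1]
      ty[2:(m - 1)] <- p[3:m, 2] - p[1:(m - 2), 2]
    }
    tl <- sqrt(tx^2 + ty^2)
    nx <- -ty / tl; ny <- tx / tl
    # cap extensions along the end tangents, constant width
    u1 <- c(tx[1], ty[1]) / tl[1]
    um <- c(tx[m], ty[m]) / tl[m]
    p_ext <- rbind(p[1, ] - cap_ext * u1, p, p[m, ] + cap_ext * um)
    nx <- c(nx[1], nx, nx[m]); ny <- c(ny[1], ny, ny[m])
    d <- c(d[1], d, d[m])
    left <- cbind(p_ext[, 1] + nx * d / 2, p_ext[, 2] + ny * d / 2)
    right <- cbind(p_ext[, 1] - nx * d / 2, p_ext[, 2] - ny * d / 2)
    plane_outline(zs[idx[1]], rbind(left, right[rev(seq_len(nrow(right))), ]))
  })
}

#' Synthetic-dataset configuration
#'
#' @param dendrites data.frame with columns `neuron_id`, `dendrite_id`,
#'   `n_spines`, and mixture columns `p1..p4` (per-dendrite class
#'   proportions, each row summing to 1).
#' @param seed integer RNG seed, recorded in the dataset metadata.
#' @param scale_nm voxel pitch (x, y, z), nm.
#' @param noise_cv diameter noise CV (`NULL` = archetype defaults).
#' @param bend_sd,step_nm skeleton geometry parameters, see [sample_spine()].
#' @param archetypes list of archetypes; defaults to [default_archetypes()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(dendrites, seed = 1, scale_nm = c(20, 20, 300),
                         noise_cv = NULL, bend_sd = 0.05, step_nm = 50,
                         archetypes = default_archetypes()) {
  dendrites <- as.data.frame(dendrites)
  need <- c("neuron_id", "dendrite_id", "n_spines",
            paste0("p", seq_along(archetypes)))
  if (!all(need %in% names(dendrites)))
    stop("dendrite table must have columns ", paste(need, collapse = ", "))
  pm <- as.matrix(dendrites[, paste0("p", seq_along(archetypes))])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9))
    stop("mixture proportions must be >= 0 and sum to 1 per dendrite")
  if (any(dendrites$n_spines < 1)) stop("n_spines must be positive")
  structure(list(dendrites = dendrites, seed = as.integer(seed),
                 scale_nm = scale_nm, noise_cv = noise_cv,
                 bend_sd = bend_sd, step_nm = step_nm,
                 archetypes = archetypes),
            class = "synth_config")
}

#' Sample a synthetic neuron dataset
#'
#' Dendrites are populated by multinomial draws from their configured class
#' mixture; every spine records its ground-truth class in
#' `notes$true_class`. Fully deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a [neuron_dataset()] with the seed echoed in `metadata`.
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  spines <- list()
  n_classes <- length(config$archetypes)
  for (r in seq_len(nrow(config$dendrites))) {
    row <- config$dendrites[r, ]
    probs <- as.numeric(row[paste0("p", seq_len(n_classes))])
    classes <- sample.int(n_classes, row$n_spines, replace = TRUE,
                          prob = probs)
    for (i in seq_along(classes)) {
      spines[[length(spines) + 1]] <- sample_spine(
        config$archetypes[[classes[i]]],
        spine_id = sprintf("%s_%s_sp%04d", row$neuron_id, row$dendrite_id, i),
        dendrite_id = row$dendrite_id, neuron_id = row$neuron_id,
        scale_nm = config$scale_nm, noise_cv = config$noise_cv,
        bend_sd = config$bend_sd, step_nm = config$step_nm,
        origin = c(0, 0, 0))
    }
  }
  neuron_dataset(spines, scale_nm = config$scale_nm,
                 metadata = list(generator = "spinemorph-synth",
                                 seed = config$seed))
}

#' Render a synthetic image stack
#'
#' Rasterizes the spine outlines plane-wise onto a pixel grid (binary
#' occupancy), blurs each plane with the 2D Lorentzian PSF, and applies
#' signal-dependent Poisson noise: the blurred intensity is taken as the
#' expected photon count per pixel times `photon_scale`. `photon_scale =
#' Inf` disables noise; `psf_fwhm = 0` disables blurring, so in that double
#' limit the output equals the rasterized ground truth.
#'
#' @param dataset a [neuron_dataset()].
#' @param psf_fwhm Lorentzian PSF full width at half maximum, nm.
#' @param photon_scale expected photons per unit intensity (Inf = noiseless).
#' @param pixel_nm lateral pixel pitch, nm.
#' @param pad_nm margin around the annotations, nm.
#' @param bounds optional list(x = c(min, max), y = c(min, max)) nm; spines
#'   outside the bounds raise an error naming the spine.
#' @return list with `stack` (blurred + noisy [spine_stack()]), `truth`
#'   (unblurred rasterization), and `planes_z` (nm of each plane).
#' @export
render_stack <- function(dataset, psf_fwhm = 50, photon_scale = Inf,
                         pixel_nm = 20, pad_nm = 200, bounds = NULL) {
  stopifnot(inherits(dataset, "neuron_dataset"))
  all_xy <- list(); all_z <- numeric(0)
  for (s in dataset$spines) {
    for (o in s$outlines) {
      if (!is.null(bounds)) {
        if (min(o$vertices[, 1]) < bounds$x[1] ||
            max(o$vertices[, 1]) > bounds$x[2] ||
            min(o$vertices[, 2]) < bounds$y[1] ||
            max(o$vertices[, 2]) > bounds$y[2])
          stop("spine ", s$skeleton$spine_id, " lies outside the stack bounds")
      }
      all_xy[[length(all_xy) + 1]] <- o$vertices
      all_z <- c(all_z, o$z)
    }
  }
  if (length(all_xy) == 0) stop("dataset has no outlines to render")
  xy <- do.call(rbind, all_xy)
  xr <- if (is.null(bounds)) range(xy[, 1]) + c(-pad_nm, pad_nm) else bounds$x
  yr <- if (is.null(bounds)) range(xy[, 2]) + c(-pad_nm, pad_nm) else bounds$y
  pitch <- dataset$scale_nm[3]
  planes_z <- seq(min(all_z), max(all_z), by = pitch)
  nx <- ceiling(diff(xr) / pixel_nm)
  ny <- ceiling(diff(yr) / pixel_nm)
  cx <- xr[1] + (seq_len(nx) - 0.5) * pixel_nm
  cy <- yr[1] + (seq_len(ny) - 0.5) * pixel_nm

  truth <- array(0, c(ny, nx, length(planes_z)))
  for (s in dataset$spines) {
    for (o in s$outlines) {
      p <- which(abs(planes_z - o$z) < pitch / 2)[1]
      ix <- which(cx >= min(o$vertices[, 1]) - pixel_nm &
                    cx <= max(o$vertices[, 1]) + pixel_nm)
      iy <- which(cy >= min(o$vertices[, 2]) - pixel_nm &
                    cy <= max(o$vertices[, 2]) + pixel_nm)
      if (length(ix) == 0 || length(iy) == 0) next
      gx <- rep(cx[ix], each = length(iy))
      gy <- rep(cy[iy], times = length(ix))
      inside <- points_in_polygon(gx, gy, o$vertices)
      sub <- truth[iy, ix, p]
      sub[matrix(inside, nrow = length(iy))] <- 1
      truth[iy, ix, p] <- sub
    }
  }

  blurred <- truth
  if (psf_fwhm > 0) {
    # generous support (+- 8 FWHM): the Lorentzian's heavy tails carry
    # real broadening; cap to the plane size for small renders
    support <- 2 * ceiling(8 * psf_fwhm / pixel_nm) + 1
    max_supp <- min(dim(truth)[1:2])
    if (support > max_supp) support <- max_supp - (1 - max_supp %% 2)
    psf <- lorentzian_psf(psf_fwhm, pixel_nm, support)
    for (p in seq_len(dim(truth)[3]))
      blurred[, , p] <- convolve_plane(truth[, , p], psf)
  }
  if (is.finite(photon_scale)) {
    lam <- pmax(blurred, 0) * photon_scale
    blurred <- array(stats::rpois(length(lam), lam) / photon_scale, dim(lam))
  }
  list(stack = spine_stack(blurred, pixel_nm, pitch),
       truth = spine_stack(truth, pixel_nm, pitch),
       planes_z = planes_z)
}
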