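# Width profiles along spine skeletons, and the ten shape descriptors.
#
# The width of a spine is measured every ~20 nm of 3D arc length,
# perpendicular to the skeleton and within the imaging plane: at each sample
# the in-plane line through the skeleton point, orthogonal to the in-plane
# projection of the local tangent, is intersected with that plane's outline
# polygon, and the diameter is the chord containing the skeleton point.
# Samples falling on plane-crossing skeleton segments (where no single
# outline applies) are linearly interpolated from their neighbors. No
# volume reconstruction is attempted: axial resolution is far poorer than
# lateral, so all widths are in-plane.

#' 3D arc length of a skeleton
#'
#' Sum of Euclidean 3D segment lengths from the attachment node to the tip;
#' the axial plane pitch contributes through z.
#'
#' @param skeleton a [spine_skeleton()] or a node matrix.
#' @return length in nm.
#' @export
arc_length_3d <- function(skeleton) {
  nodes <- if (inherits(skeleton, "spine_skeleton")) skeleton$nodes
           else as.matrix(skeleton)
  if (nrow(nodes) < 2) stop("arc length needs >= 2 nodes")
  sum(sqrt(rowSums(diff(nodes)^2)))
}

#' Compute the width profile of one spine
#'
#' @param annotation a [spine_annotation()] with `complete = TRUE`.
#' @param step_nm nominal arc-length sampling step, nm.
#' @param z_tol tolerance for matching sample planes to outline planes, nm.
#' @return a `width_profile`: list with `s` (arc positions, nm, strictly
#'   increasing from 0), `d` (diameters, nm), `region` (per-sample
#'   `"neck"`/`"head"`/`"other"`), and `spine_id`.
#' @export
compute_width_profile <- function(annotation, step_nm = 20, z_tol = 1e-6) {
  stopifnot(inherits(annotation, "spine_annotation"))
  if (!annotation$complete)
    stop("spine ", annotation$skeleton$spine_id,
         " is flagged incomplete and excluded from morphometry")
  sk <- annotation$skeleton
  nodes <- sk$nodes
  seg <- diff(nodes)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0))
    stop("zero-length skeleton segment (spine ", sk$spine_id, ")")
  s_nodes <- c(0, cumsum(seg_len))
  total <- s_nodes[length(s_nodes)]

  s <- seq(0, total, by = step_nm)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)

  # containing segment per sample (samples at node positions take the
  # following segment, except the terminal sample)
  seg_idx <- pmin(findInterval(s, s_nodes, rightmost.closed = TRUE),
                  nrow(seg))
  frac <- (s - s_nodes[seg_idx]) / seg_len[seg_idx]
  px <- nodes[seg_idx, 1] + frac * seg[seg_idx, 1]
  py <- nodes[seg_idx, 2] + frac * seg[seg_idx, 2]
  pz <- nodes[seg_idx, 3] + frac * seg[seg_idx, 3]
  in_plane <- abs(seg[seg_idx, 3]) <= z_tol

  outline_z <- vapply(annotation$outlines, function(o) o$z, 0)
  node_planes <- unique(nodes[, 3][c(abs(seg[, 3]) <= z_tol, FALSE) |
                                     c(FALSE, abs(seg[, 3]) <= z_tol)])
  for (zp in node_planes) {
    if (!any(abs(outline_z - zp) <= max(z_tol, 1e-6)))
      stop("no outline on plane z = ", zp, " (spine ", sk$spine_id, ")")
  }

  d <- rep(NA_real_, length(s))
  for (oi in seq_along(annotation$outlines)) {
    o <- annotation$outlines[[oi]]
    sel <- which(in_plane & abs(pz - o$z) <= max(z_tol, 1e-6))
    if (length(sel) == 0) next
    # in-plane perpendicular of the containing segment's tangent
    txy <- seg[seg_idx[sel], 1:2, drop = FALSE]
    tl <- sqrt(rowSums(txy^2))
    for (k in seq_along(sel)) {
      i <- sel[k]
      if (tl[k] == 0) next  # purely axial segment: leave for interpolation
      ch <- polygon_chord(px[i], py[i],
                          -txy[k, 2] / tl[k], txy[k, 1] / tl[k],
                          o$vertices)
      if (is.na(ch))
        stop("skeleton point outside its outline at s = ", round(s[i], 2),
             " nm (spine ", sk$spine_id, ")")
      d[i] <- ch
    }
  }

  if (all(is.na(d)))
    stop("no measurable samples (spine ", sk$spine_id, ")")
  # interpolate samples that fell between planes
  if (anyNA(d)) {
    ok <- !is.na(d)
    d <- stats::approx(s[ok], d[ok], xout = s, rule = 2)$y
  }

  # region per sample: nearest labeled node along arc; "other" if none
  region <- rep("other", length(s))
  lab_idx <- which(sk$region_labels != "unlabeled")
  if (length(lab_idx) > 0) {
    nearest <- lab_idx[apply(abs(outer(s, s_nodes[lab_idx], `-`)), 1,
                             which.min)]
    region <- sk$region_labels[nearest]
  }
  structure(list(s = s, d = d, region = region, spine_id = sk$spine_id),
            class = "width_profile")
}

#' The ten shape descriptors of one spine
#'
#' * head / neck diameter: largest diameter among head samples / smallest
#'   among neck samples, and their ratio;
#' * spine length: the final 3D arc position;
#' * spine / neck / head area: the integral of the diameter along the arc,
#'   approximated as the sum of diameters times the actual sampling
#'   intervals (midpoint weights), restricted to the region's samples;
#' * cv_spine / cv_neck / cv_head: coefficient of variation (sd / mean) of
#'   the diameters over all / neck / head samples.
#'
#' Spines without labeled neck or head samples keep length, spine area and
#' cv_spine; the region-specific descriptors are `NA` (missing by contract).
#'
#' @param profile a `width_profile` from [compute_width_profile()].
#' @return a one-row data.frame with `spine_id` and the ten descriptors.
#' @export
compute_descriptors <- function(profile) {
  s <- profile$s; d <- profile$d; region <- profile$region
  n <- length(s)
  if (n < 2) stop("profile too short (spine ", profile$spine_id, ")")
  # midpoint (trapezoid-equivalent) interval weights
  w <- c(diff(s)[1] / 2,
         if (n > 2) (s[3:n] - s[1:(n - 2)]) / 2 else NULL,
         diff(s)[n - 1] / 2)
  neck <- region == "neck"
  head <- region == "head"
  cv <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / mean(x)
  head_d <- if (any(head)) max(d[head]) else NA_real_
  neck_d <- if (any(neck)) min(d[neck]) else NA_real_
  data.frame(
    spine_id = profile$spine_id,
    head_diameter = head_d,
    neck_diameter = neck_d,
    head_neck_ratio = head_d / neck_d,
    spine_length = s[n],
    spine_area = sum(d * w),
    neck_area = if (any(neck)) sum(d[neck] * w[neck]) else NA_real_,
    head_area = if (any(head)) sum(d[head] * w[head]) else NA_real_,
    cv_spine = cv(d),
    cv_neck = if (any(neck)) cv(d[neck]) else NA_real_,
    cv_head = if (any(head)) cv(d[head]) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Profiles and descriptors for every complete spine of a dataset
#'
#' @param dataset a [neuron_dataset()].
#' @param step_nm profile sampling step, nm.
#' @return list with `profiles` (named list of width profiles),
#'   `descriptors` (data.frame, one row per complete spine), and
#'   `n_excluded` (spines skipped because `complete = FALSE`).
#' @export
measure_dataset <- function(dataset, step_nm = 20) {
  stopifnot(inherits(dataset, "neuron_dataset"))
  keep <- vapply(dataset$spines, function(s) s$complete, TRUE)
  profiles <- lapply(dataset$spines[keep], compute_width_profile,
                     step_nm = step_nm)
  names(profiles) <- vapply(profiles, function(p) p$spine_id, "")
  descriptors <- do.call(rbind, lapply(profiles, compute_descriptors))
  rownames(descriptors) <- NULL
  list(profiles = profiles, descriptors = descriptors,
       n_excluded = sum(!keep))
}

#' @rdname measure_dataset
#' @param ... passed to [measure_dataset()].
#' @export
descriptor_table <- function(dataset, ...) measure_dataset(dataset, ...)$descriptors
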