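# Profile-based spine classification: 175-dimensional feature vectors
# (100 resampled diameters + the spine length repeated 75 times, rescaled so
# the grand mean of the length dimensions matches the grand mean of the
# diameter dimensions), Ward hierarchical clustering on Euclidean distances,
# and Davies-Bouldin selection of the class number.

#' Resample a width profile to n equally spaced points
#'
#' Linear interpolation of the diameter at `n` equally spaced arc positions
#' spanning `[0, spine_length]`; index 1 is the dendrite attachment, index
#' `n` the tip.
#'
#' @param profile a `width_profile` (or any list with `s` and `d`).
#' @param n number of output samples.
#' @return numeric vector of `n` diameters, nm.
#' @export
resample_profile <- function(profile, n = 100) {
  if (length(profile$s) < 2) stop("profile needs >= 2 samples")
  stats::approx(profile$s, profile$d,
                xout = seq(profile$s[1], profile$s[length(profile$s)],
                           length.out = n))$y
}

#' Build the 175-dimensional feature matrix
#'
#' Dimensions 1-100 hold the resampled diameter profile (nm); dimensions
#' 101-(100+`repeats`) hold the spine length, rescaled by
#' `mean(all diameters) / mean(lengths)` so both blocks carry equal weight,
#' repeated to balance its influence against the 100 shape dimensions.
#'
#' @param profiles list of width profiles (>= 2).
#' @param lengths numeric spine lengths, nm; defaults to the final arc
#'   position of each profile.
#' @param n_profile resampling points (default 100).
#' @param repeats number of repeated length dimensions (default 75).
#' @return list with `features` (matrix, spines x dims, rownames = spine
#'   ids) and `length_scale_factor`.
#' @export
build_feature_matrix <- function(profiles, lengths = NULL, n_profile = 100,
                                 repeats = 75) {
  if (length(profiles) < 2) stop("need >= 2 spines to build features")
  P <- t(vapply(profiles, resample_profile, numeric(n_profile),
                n = n_profile))
  if (is.null(lengths))
    lengths <- vapply(profiles, function(p) p$s[length(p$s)], 0)
  if (mean(lengths) <= 0) stop("mean spine length must be positive")
  factor <- mean(P) / mean(lengths)
  features <- cbind(P, matrix(lengths * factor, nrow(P), repeats))
  rownames(features) <- vapply(profiles, function(p) p$spine_id, "")
  list(features = features, length_scale_factor = factor)
}

#' Ward hierarchical clustering cut at k classes
#'
#' Agglomerative clustering on Euclidean distances with Ward's
#' minimum-variance criterion (each merge minimizes the increase in total
#' within-cluster sum of squares), cut at `k` clusters. Deterministic given
#' the input order; equal-criterion merges resolve to the earliest pair in
#' the distance ordering.
#'
#' @param features numeric matrix, spines x dims.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer labels in `1..k`, named by rownames of `features`;
#'   the `hclust` tree is attached as attribute `"tree"`.
#' @export
ward_cluster <- function(features, k) {
  n <- nrow(features)
  if (k > n) stop("k = ", k, " exceeds the number of spines (", n, ")")
  if (k < 1) stop("k must be >= 1")
  tree <- stats::hclust(stats::dist(features), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Davies-Bouldin index of a clustering
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij` with `S_i` the mean
#' Euclidean distance of cluster members to their centroid and `M_ij` the
#' distance between centroids i and j. Lower is better.
#'
#' @param features numeric matrix, spines x dims.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return the index (scalar).
#' @export
davies_bouldin <- function(features, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("Davies-Bouldin needs >= 2 clusters")
  cent <- vapply(seq_len(k), function(i)
    colMeans(features[labels == i, , drop = FALSE]),
    numeric(ncol(features)))
  centroids <- if (is.matrix(cent)) t(cent) else matrix(cent, ncol = 1)
  S <- vapply(seq_len(k), function(i) {
    m <- features[labels == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, centroids[i, ])^2)))
  }, 0)
  M <- as.matrix(stats::dist(centroids))
  if (any(M[upper.tri(M)] == 0))
    stop("coincident centroids: Davies-Bouldin undefined")
  R <- outer(S, S, `+`) / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Select the number of classes by Davies-Bouldin
#'
#' Cuts one Ward tree at every candidate `k` and returns the `k` minimizing
#' the Davies-Bouldin index (smallest `k` on ties).
#'
#' @param features numeric matrix, spines x dims.
#' @param k_range candidate class counts (within `[2, n - 1]`).
#' @return selected `k`, with the full index curve as attribute
#'   `"db_curve"` (named numeric) and the tree as `"tree"`.
#' @export
select_k <- function(features, k_range = 2:8) {
  n <- nrow(features)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty candidate range for k")
  tree <- stats::hclust(stats::dist(features), method = "ward.D2")
  db <- vapply(k_range, function(k)
    davies_bouldin(features, stats::cutree(tree, k = k)), 0)
  names(db) <- k_range
  k <- k_range[which.min(db)]
  attr(k, "db_curve") <- db
  attr(k, "tree") <- tree
  k
}

#' Fit the full cluster model
#'
#' Convenience wrapper: features, Davies-Bouldin selection over `k_range`,
#' labels at the selected `k`.
#'
#' @param profiles list of width profiles.
#' @param lengths optional spine lengths (nm).
#' @param k_range candidate class counts.
#' @param k fixed class count (skips selection when given).
#' @return a `cluster_model`: list with `labels` (named, in `1..k`), `k`,
#'   `db_curve`, `length_scale_factor`, `features`, and the `hclust` `tree`.
#' @export
cluster_spines <- function(profiles, lengths = NULL, k_range = 2:8, k = NULL) {
  fm <- build_feature_matrix(profiles, lengths)
  if (is.null(k)) {
    ksel <- select_k(fm$features, k_range)
    tree <- attr(ksel, "tree")
    db <- attr(ksel, "db_curve")
    k <- as.integer(ksel)
  } else {
    tree <- stats::hclust(stats::dist(fm$features), method = "ward.D2")
    db <- NULL
  }
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, k = k, db_curve = db,
                 length_scale_factor = fm$length_scale_factor,
                 features = fm$features, tree = tree),
            class = "cluster_model")
}

#' Per-class mean profiles
#'
#' Element-wise mean of the 100-point resampled profiles of each class,
#' together with the class mean spine length (the arc axis of the mean
#' profile is `seq(0, mean_length, length.out = 100)`).
#'
#' @param profiles list of width profiles.
#' @param lengths optional spine lengths, nm.
#' @param labels integer class labels, one per profile.
#' @return list per class: `class`, `n`, `mean_profile` (100 values),
#'   `mean_length`.
#' @export
class_mean_profiles <- function(profiles, lengths = NULL, labels) {
  if (length(labels) != length(profiles))
    stop("one label per profile required")
  if (is.null(lengths))
    lengths <- vapply(profiles, function(p) p$s[length(p$s)], 0)
  P <- t(vapply(profiles, resample_profile, numeric(100)))
  lapply(sort(unique(labels)), function(cl) {
    sel <- labels == cl
    if (!any(sel)) stop("class ", cl, " is empty")
    list(class = cl, n = sum(sel),
         mean_profile = colMeans(P[sel, , drop = FALSE]),
         mean_length = mean(lengths[sel]))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (1 = identical partitions up to renaming, ~0 = chance).
#'
#' @param a,b integer label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
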