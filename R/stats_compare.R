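# Dendrite-heterogeneity statistics: Pearson chi-square tests on
# dendrite x class contingency tables (omnibus, per-neuron, and pairwise
# with Bonferroni correction), Kruskal-Wallis tests on the descriptors with
# Dunn's pairwise post hoc, and a shuffle control that reassigns spines to
# dendrites while keeping per-dendrite spine counts fixed.

#' Dendrite x class count table
#'
#' @param index data.frame with columns `spine_id`, `dendrite_id`,
#'   `neuron_id` (e.g. [dataset_index()]), or a [neuron_dataset()].
#' @param labels named integer class labels keyed by spine_id.
#' @param scope `"all"`, a neuron id, or a character vector of dendrite ids.
#' @return a `class_distribution`: list with `counts` (dendrite x class
#'   integer matrix), `fractions_by_dendrite` (rows sum to 1),
#'   `fractions_by_class` (columns sum to 1), and `neuron` (dendrite ->
#'   neuron map).
#' @export
class_count_table <- function(index, labels, scope = "all") {
  if (inherits(index, "neuron_dataset")) index <- dataset_index(index)
  if (length(scope) == 1 && scope == "all") {
    sel <- rep(TRUE, nrow(index))
  } else if (length(scope) == 1 && scope %in% index$neuron_id) {
    sel <- index$neuron_id == scope
  } else {
    sel <- index$dendrite_id %in% scope
  }
  index <- index[sel, , drop = FALSE]
  miss <- setdiff(index$spine_id, names(labels))
  if (length(miss) > 0)
    stop("unlabeled spine(s) in scope: ", paste(utils::head(miss, 5),
                                                collapse = ", "))
  cls <- labels[index$spine_id]
  counts <- table(dendrite = index$dendrite_id, class = cls)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  structure(list(
    counts = counts,
    fractions_by_dendrite = counts / rowSums(counts),
    fractions_by_class = sweep(counts, 2, colSums(counts), `/`),
    neuron = vapply(rownames(counts), function(d)
      index$neuron_id[match(d, index$dendrite_id)], "")
  ), class = "class_distribution")
}

#' Pearson chi-square test of homogeneity
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins, df =
#' `(r - 1)(c - 1)` after dropping all-zero columns, upper-tail p from the
#' chi-square distribution. No continuity correction. A warning is attached
#' when any expected count is below 5.
#'
#' @param table integer contingency matrix (dendrites x classes) or a
#'   `class_distribution`.
#' @param comparison identifier string carried into the result.
#' @return one-row data.frame: test, comparison, statistic, df, p,
#'   p_adjusted (= p here), low_expected.
#' @export
pearson_chi_square <- function(table, comparison = "omnibus") {
  if (inherits(table, "class_distribution")) table <- table$counts
  table <- as.matrix(table)
  zero_row <- rowSums(table) == 0
  if (any(zero_row))
    stop("dendrite(s) with zero spines: ",
         paste(rownames(table)[zero_row], collapse = ", "))
  table <- table[, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2x2 table after dropping empty classes")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(test = "pearson_chi_square", comparison = comparison,
             statistic = stat, df = df, p = p, p_adjusted = p,
             low_expected = any(E < 5), stringsAsFactors = FALSE)
}

#' Pairwise chi-square tests between dendrites with Bonferroni correction
#'
#' Runs the Pearson chi-square on every dendrite-pair sub-table and
#' multiplies raw p-values by the number of pairs in the family (all pairs
#' of the supplied table; restrict the table to one neuron for a
#' within-neuron family). Per-pair errors are recorded, not propagated.
#'
#' @param table dendrite x class counts or a `class_distribution`.
#' @param alpha display significance level.
#' @return data.frame with one row per pair: dendrite ids, statistic, df,
#'   p, p_adjusted = min(1, p * m), and a `band` in
#'   `c("ns", "*", "**", "***")` at adjusted 0.05 / 0.01 / 0.001.
#' @export
pairwise_dendrite_tests <- function(table, alpha = 0.05) {
  if (inherits(table, "class_distribution")) table <- table$counts
  table <- as.matrix(table)
  nd <- nrow(table)
  if (nd < 2) stop("need >= 2 dendrites")
  pairs <- utils::combn(nd, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- tryCatch(
      pearson_chi_square(table[c(i1, i2), , drop = FALSE],
                         comparison = paste(rownames(table)[i1],
                                            rownames(table)[i2], sep = " vs ")),
      error = function(e) data.frame(
        test = "pearson_chi_square",
        comparison = paste(rownames(table)[i1], rownames(table)[i2],
                           sep = " vs "),
        statistic = NA_real_, df = NA_real_, p = NA_real_,
        p_adjusted = NA_real_, low_expected = NA,
        stringsAsFactors = FALSE))
    res$dendrite_1 <- rownames(table)[i1]
    res$dendrite_2 <- rownames(table)[i2]
    res
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * m)
  out$band <- significance_band(out$p_adjusted)
  out
}

#' @noRd
significance_band <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))))
}

#' Kruskal-Wallis test across dendrites with Dunn's post hoc
#'
#' Rank-based k-group test of identical distributions, with midranks for
#' ties and the standard tie correction; the H statistic is referred to a
#' chi-square distribution with `groups - 1` df. Pairwise follow-up uses
#' Dunn's z-tests on mean ranks with Bonferroni correction over the pairs.
#' Groups whose values are all missing are dropped with a warning.
#'
#' @param values numeric descriptor values.
#' @param groups group (dendrite) identifier per value.
#' @param descriptor name carried into the results.
#' @return list with `omnibus` (one-row data.frame) and `pairwise`
#'   (data.frame of Dunn comparisons with bands at 0.05 / 0.01 / 0.001).
#' @export
kruskal_wallis_by_dendrite <- function(values, groups,
                                       descriptor = "descriptor") {
  groups <- as.character(groups)
  keep_group <- tapply(values, groups, function(v) any(!is.na(v)))
  dropped <- names(keep_group)[!keep_group]
  if (length(dropped) > 0)
    warning("dropping group(s) with all-missing values: ",
            paste(dropped, collapse = ", "))
  ok <- !is.na(values) & groups %in% names(keep_group)[keep_group]
  values <- values[ok]; groups <- groups[ok]
  gl <- unique(groups)
  if (length(gl) < 2) stop("need >= 2 groups with data")

  n <- length(values)
  r <- rank(values)  # midranks
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(Rg^2 / ng) - 3 * (n + 1)
  C <- 1 - tie_term / (n^3 - n)
  if (C > 0) H <- H / C
  df <- length(gl) - 1
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  omnibus <- data.frame(test = "kruskal_wallis", comparison = descriptor,
                        statistic = H, df = df, p = p, p_adjusted = p,
                        stringsAsFactors = FALSE)

  # Dunn's z on mean ranks, tie-corrected pooled variance
  mean_rank <- Rg / ng
  pairs <- utils::combn(sort(names(ng)), 2)
  m <- ncol(pairs)
  sigma2 <- (n * (n + 1) / 12) - tie_term / (12 * (n - 1))
  pw <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    z <- (mean_rank[g1] - mean_rank[g2]) /
      sqrt(sigma2 * (1 / ng[g1] + 1 / ng[g2]))
    praw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(test = "dunn", comparison = paste(descriptor, g1, "vs", g2),
               group_1 = g1, group_2 = g2, statistic = unname(z),
               df = NA_real_, p = unname(praw),
               p_adjusted = min(1, unname(praw) * m),
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pw)
  rownames(pairwise) <- NULL
  pairwise$band <- significance_band(pairwise$p_adjusted)
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Shuffle control for the heterogeneity tests
#'
#' Randomly reassigns spines to dendrites, keeping the number of spines on
#' every dendrite constant (a permutation of the dendrite column), and
#' reruns the omnibus chi-square on the class table and, optionally, the
#' Kruskal-Wallis battery on the descriptors. Reports per-shuffle raw
#' p-values and the fraction significant at `alpha`.
#'
#' @param index data.frame with `spine_id`, `dendrite_id` (e.g.
#'   [dataset_index()]) or a [neuron_dataset()].
#' @param labels named class labels keyed by spine_id.
#' @param descriptors optional descriptor data.frame (keyed by spine_id);
#'   when given, Kruskal-Wallis is rerun per descriptor per shuffle.
#' @param n_shuffles number of shuffles (0 = empty summary).
#' @param alpha significance level for the reported rejection fractions.
#' @param seed RNG seed.
#' @return list with `chi_square_p` (numeric per shuffle),
#'   `chi_square_reject_rate`, and when descriptors are supplied
#'   `kruskal_reject_rate` (named per descriptor).
#' @export
shuffle_control <- function(index, labels, descriptors = NULL,
                            n_shuffles = 1000, alpha = 0.05, seed = 1) {
  if (inherits(index, "neuron_dataset")) index <- dataset_index(index)
  if (n_shuffles == 0)
    return(list(chi_square_p = numeric(0),
                chi_square_reject_rate = NA_real_))
  set.seed(seed)
  cls <- labels[index$spine_id]
  desc_cols <- if (!is.null(descriptors))
    setdiff(names(descriptors), "spine_id") else character(0)
  if (!is.null(descriptors))
    descriptors <- descriptors[match(index$spine_id, descriptors$spine_id), ]
  chi_p <- numeric(n_shuffles)
  kw_rej <- stats::setNames(numeric(length(desc_cols)), desc_cols)
  for (b in seq_len(n_shuffles)) {
    perm <- sample.int(nrow(index))
    dend <- index$dendrite_id[perm]  # counts per dendrite unchanged
    tab <- table(dend, cls)
    chi_p[b] <- pearson_chi_square(as.matrix(tab))$p
    for (dc in desc_cols) {
      kw <- suppressWarnings(
        kruskal_wallis_by_dendrite(descriptors[[dc]], dend, dc))
      kw_rej[dc] <- kw_rej[dc] + (kw$omnibus$p < alpha)
    }
  }
  out <- list(chi_square_p = chi_p,
              chi_square_reject_rate = mean(chi_p < alpha))
  if (length(desc_cols) > 0) out$kruskal_reject_rate <- kw_rej / n_shuffles
  out
}

#' Full heterogeneity battery for a labeled dataset
#'
#' The omnibus chi-square across all dendrites, per-neuron chi-squares,
#' pairwise dendrite tests (within-neuron and all-pairs families), and
#' per-descriptor Kruskal-Wallis tests across dendrites within each neuron.
#'
#' @param index [dataset_index()]-style data.frame or [neuron_dataset()].
#' @param labels named class labels keyed by spine_id.
#' @param descriptors descriptor data.frame keyed by spine_id (optional).
#' @param alpha display significance level.
#' @return list of data.frames: `omnibus`, `per_neuron`,
#'   `pairwise_within_neuron`, `pairwise_all`, `kruskal`.
#' @export
heterogeneity_tests <- function(index, labels, descriptors = NULL,
                                alpha = 0.05) {
  if (inherits(index, "neuron_dataset")) index <- dataset_index(index)
  tab_all <- class_count_table(index, labels, "all")
  omnibus <- pearson_chi_square(tab_all, "all dendrites")
  neurons <- unique(index$neuron_id)
  per_neuron <- do.call(rbind, lapply(neurons, function(nid) {
    sub <- class_count_table(index, labels, nid)
    if (nrow(sub$counts) < 2) return(NULL)
    pearson_chi_square(sub, paste("neuron", nid))
  }))
  pw_within <- do.call(rbind, lapply(neurons, function(nid) {
    sub <- class_count_table(index, labels, nid)
    if (nrow(sub$counts) < 2) return(NULL)
    res <- pairwise_dendrite_tests(sub, alpha)
    res$neuron_id <- nid
    res
  }))
  pw_all <- pairwise_dendrite_tests(tab_all, alpha)
  kw <- NULL
  if (!is.null(descriptors)) {
    merged <- merge(index, descriptors, by = "spine_id")
    desc_cols <- setdiff(names(descriptors), "spine_id")
    kw <- do.call(rbind, lapply(neurons, function(nid) {
      sub <- merged[merged$neuron_id == nid, ]
      if (length(unique(sub$dendrite_id)) < 2) return(NULL)
      do.call(rbind, lapply(desc_cols, function(dc) {
        res <- suppressWarnings(
          kruskal_wallis_by_dendrite(sub[[dc]], sub$dendrite_id,
                                     paste0(nid, ":", dc)))
        res$omnibus
      }))
    }))
    if (!is.null(kw)) {
      # family: the descriptors tested within each neuron
      kw$p_adjusted <- pmin(1, kw$p * length(desc_cols))
    }
  }
  list(omnibus = omnibus, per_neuron = per_neuron,
       pairwise_within_neuron = pw_within, pairwise_all = pw_all,
       kruskal = kw)
}
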