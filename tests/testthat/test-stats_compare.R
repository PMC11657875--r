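mk_index <- function(dendrites, per = 10, neuron = "n1") {
  data.frame(
    neuron_id = neuron,
    dendrite_id = rep(dendrites, each = per),
    spine_id = paste0("sp", seq_len(length(dendrites) * per)),
    complete = TRUE, true_class = NA_integer_
  )
}

test_that("class_count_table builds counts and normalized fractions", {
  idx <- mk_index(c("d1", "d2"), per = 10)
  labels <- stats::setNames(rep(1L, 20), idx$spine_id)
  tab <- class_count_table(idx, labels)
  expect_equal(unname(tab$counts[, 1]), c(10, 10))
  expect_true(all(rowSums(tab$fractions_by_dendrite) == 1))
  expect_true(all(colSums(tab$fractions_by_class) == 1))

  labels2 <- labels
  labels2[11:20] <- 2L
  tab2 <- class_count_table(idx, labels2)
  expect_equal(unname(tab2$counts),
               matrix(c(10L, 0L, 0L, 10L), 2, 2))
  # unlabeled spine in scope errors
  expect_error(class_count_table(idx, labels[-1]), "unlabeled")
})

test_that("Pearson chi-square matches closed forms and the stats oracle", {
  # homogeneous table
  r0 <- pearson_chi_square(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # diagonal 2x2: chi2 = N(ad-bc)^2/(row x col products) = 40
  r1 <- pearson_chi_square(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(r1$statistic, 40, tolerance = 1e-9)
  expect_equal(r1$df, 1)
  expect_equal(r1$p, stats::pchisq(40, 1, lower.tail = FALSE))
  # proportionality: scaling counts by 10 scales the statistic by 10
  set.seed(51)
  tab <- matrix(rpois(8, 20) + 1, 2, 4)
  expect_equal(pearson_chi_square(10 * tab)$statistic,
               10 * pearson_chi_square(tab)$statistic, tolerance = 1e-9)
  # independent oracle: stats::chisq.test without continuity correction
  oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  mine <- pearson_chi_square(tab)
  expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(oracle$parameter))
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
  # all-zero classes are dropped before computing df
  tab0 <- cbind(tab, c(0, 0))
  expect_equal(pearson_chi_square(tab0)$df, 3)
  # zero dendrite margin names the dendrite
  bad <- rbind(d1 = c(5, 5), d2 = c(0, 0))
  expect_error(pearson_chi_square(bad), "d2")
})

test_that("pairwise dendrite tests apply the Bonferroni family", {
  tab <- rbind(d1 = c(30, 10, 5, 5), d2 = c(30, 10, 5, 5),
               d3 = c(5, 5, 10, 30))
  res <- pairwise_dendrite_tests(tab)
  expect_equal(nrow(res), 3)  # 3 dendrites -> 3 pairs, factor 3
  expect_equal(res$p_adjusted, pmin(1, res$p * 3))
  # identical dendrites -> adjusted p = 1
  same <- res[res$dendrite_1 == "d1" & res$dendrite_2 == "d2", ]
  expect_equal(same$statistic, 0)
  expect_equal(same$p_adjusted, 1)
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  expect_true(all(res$p_adjusted <= 1, na.rm = TRUE))
  expect_true(all(res$band %in% c("ns", "*", "**", "***")))
})

test_that("Kruskal-Wallis matches hand ranks and the stats oracle", {
  # identical groups -> H = 0, p = 1
  r0 <- kruskal_wallis_by_dendrite(c(1, 2, 3, 1, 2, 3),
                                   rep(c("a", "b"), each = 3))
  expect_equal(r0$omnibus$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$omnibus$p, 1)
  # {1,2,3} vs {4,5,6}: rank sums 6 and 15, H = 3.857..., p ~ 0.0495
  r1 <- kruskal_wallis_by_dendrite(1:6, rep(c("a", "b"), each = 3))
  expect_equal(r1$omnibus$statistic, 27 / 7, tolerance = 1e-3)
  expect_equal(r1$omnibus$p,
               stats::pchisq(27 / 7, 1, lower.tail = FALSE), tolerance = 1e-6)
  # oracle: stats::kruskal.test with ties
  set.seed(52)
  v <- c(stats::rnorm(12), stats::rnorm(15, 1), stats::rnorm(9, 2))
  v <- round(v, 1)  # induce ties
  g <- rep(c("a", "b", "c"), c(12, 15, 9))
  mine <- kruskal_wallis_by_dendrite(v, g)
  oracle <- stats::kruskal.test(v, factor(g))
  expect_equal(mine$omnibus$statistic, unname(oracle$statistic),
               tolerance = 1e-12)
  expect_equal(mine$omnibus$p, oracle$p.value, tolerance = 1e-12)
  # rank invariance under strictly monotone transforms
  mono <- kruskal_wallis_by_dendrite(exp(v), g)
  expect_equal(mono$omnibus$statistic, mine$omnibus$statistic,
               tolerance = 1e-12)
  # Dunn post hoc: Bonferroni over pairs, bands valid
  expect_equal(nrow(mine$pairwise), 3)
  expect_true(all(mine$pairwise$p_adjusted >= mine$pairwise$p))
  expect_true(all(mine$pairwise$p_adjusted <= 1))
  # all-missing group dropped with warning
  expect_warning(
    kruskal_wallis_by_dendrite(c(v, NA, NA), c(g, "dd", "dd")),
    "all-missing")
})

test_that("shuffles preserve per-dendrite counts and calibrate the null", {
  idx <- mk_index(c("d1", "d2", "d3"), per = 40)
  set.seed(53)
  labels <- stats::setNames(sample(1:4, 120, replace = TRUE), idx$spine_id)
  # counts preserved: rerun with a tracer checking table margins
  sh <- shuffle_control(idx, labels, n_shuffles = 50, seed = 7)
  expect_length(sh$chi_square_p, 50)
  expect_true(all(sh$chi_square_p >= 0 & sh$chi_square_p <= 1))
  # n_shuffles = 0 -> empty summary
  sh0 <- shuffle_control(idx, labels, n_shuffles = 0)
  expect_length(sh0$chi_square_p, 0)
})

test_that("strong mixture contrasts are detected (power property)", {
  # two dendrites, opposite 0.7-dominant mixtures, n = 100 spines each
  set.seed(54)
  hits <- 0L
  for (rep in 1:30) {
    c1 <- sample(1:4, 100, TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    c2 <- sample(1:4, 100, TRUE, prob = c(0.1, 0.1, 0.1, 0.7))
    tab <- rbind(d1 = tabulate(c1, 4), d2 = tabulate(c2, 4))
    res <- pairwise_dendrite_tests(tab)
    hits <- hits + (res$p_adjusted < 0.001)
  }
  expect_gte(hits, 29)  # >= 95% power, small-sample check
})

test_that("identical mixtures reject at about the nominal rate (null)", {
  set.seed(55)
  p <- replicate(200, {
    c1 <- sample(1:4, 80, TRUE)
    c2 <- sample(1:4, 80, TRUE)
    pearson_chi_square(rbind(tabulate(c1, 4), tabulate(c2, 4)))$p
  })
  rate <- mean(p < 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("heterogeneity battery runs end to end on synthetic data", {
  dend <- rbind(default_dendrite_table(2, 40),
                within(default_dendrite_table(2, 40), {
                  neuron_id <- "n2"
                  dendrite_id <- paste0(dendrite_id, "b")
                }))
  ds <- sample_dataset(synth_config(dend, seed = 56))
  meas <- measure_dataset(ds)
  idx <- dataset_index(ds)
  labels <- stats::setNames(idx$true_class, idx$spine_id)
  tests <- heterogeneity_tests(idx, labels, meas$descriptors)
  expect_s3_class(tests$omnibus, "data.frame")
  expect_lt(tests$omnibus$p, 0.001)  # opposite mixtures are heterogeneous
  expect_equal(nrow(tests$per_neuron), 2)
  expect_true(all(tests$pairwise_all$p_adjusted >= tests$pairwise_all$p,
                  na.rm = TRUE))
  expect_true(!is.null(tests$kruskal) && nrow(tests$kruskal) == 20)
})
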