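test_that("a straight cylinder spine measures constant 400 nm width", {
  ann <- cylinder_annotation(2000, 400)
  pr <- compute_width_profile(ann, step_nm = 20)
  expect_equal(length(pr$s), 101)
  expect_true(all(abs(pr$d - 400) < 1e-6))
  expect_equal(pr$s[1], 0)
  expect_true(all(diff(pr$s) > 0))
  expect_true(all(diff(pr$s) <= 1.5 * 20 + 1e-9))
})

test_that("a linear cone halves its width at mid-arc", {
  ann <- cone_annotation(2000, 600)
  pr <- compute_width_profile(ann, step_nm = 20)
  expect_equal(pr$d[pr$s == 1000], 300, tolerance = 10 / 300)
})

test_that("profiles match the 1 nm rasterization oracle on random spines", {
  set.seed(31)
  arch <- default_archetypes()
  for (rep in 1:12) {
    a <- arch[[((rep - 1) %% 4) + 1]]
    sp <- sample_spine(a)
    pr <- compute_width_profile(sp, step_nm = 20)
    ora <- oracle_profile(sp, step_nm = 20)
    measurable <- !is.na(ora$d)
    expect_gt(sum(measurable), 0.5 * length(ora$d))
    expect_lt(max(abs(pr$d[measurable] - ora$d[measurable])), 2)
  }
})

test_that("3D arc length follows the anisotropic geometry", {
  expect_equal(arc_length_3d(rbind(c(0, 0, 0), c(400, 0, 0))), 400)
  # adjacent planes: 3-4-5 triangle with 300 nm pitch
  expect_equal(arc_length_3d(rbind(c(0, 0, 0), c(400, 0, 300))), 500)
  # refinement convergence on a curved skeleton
  t <- seq(0, pi / 2, length.out = 20)
  coarse <- cbind(1000 * cos(t), 1000 * sin(t), 0)
  t2 <- seq(0, pi / 2, length.out = 400)
  fine <- cbind(1000 * cos(t2), 1000 * sin(t2), 0)
  expect_lt(abs(arc_length_3d(fine) - arc_length_3d(coarse)) /
              arc_length_3d(fine), 0.01)
})

test_that("descriptors match closed forms on constructed profiles", {
  # constant 400 nm over 2000 nm, half neck half head
  s <- seq(0, 2000, by = 20)
  region <- ifelse(s <= 1000, "neck", "head")
  pr <- structure(list(s = s, d = rep(400, length(s)), region = region,
                       spine_id = "c"), class = "width_profile")
  d <- compute_descriptors(pr)
  expect_equal(d$spine_area, 800000)
  expect_equal(d$cv_spine, 0)
  expect_equal(d$head_neck_ratio, 1)
  expect_equal(d$spine_length, 2000)

  # min/max extraction
  pr2 <- structure(list(s = seq(0, 100, length.out = 6),
                        d = c(120, 100, 140, 350, 400, 380),
                        region = c("neck", "neck", "neck", "head", "head", "head"),
                        spine_id = "m"), class = "width_profile")
  d2 <- compute_descriptors(pr2)
  expect_equal(d2$neck_diameter, 100)
  expect_equal(d2$head_diameter, 400)
  expect_equal(d2$head_neck_ratio, 4)

  # triangular profile: Riemann sum within 1% of the analytic integral
  s3 <- seq(0, 2000, by = 20)
  pr3 <- structure(list(s = s3, d = 600 * (1 - s3 / 2000),
                        region = rep("other", length(s3)), spine_id = "t"),
                   class = "width_profile")
  expect_equal(compute_descriptors(pr3)$spine_area, 600000,
               tolerance = 0.01)
})

test_that("descriptors without labeled regions are missing by contract", {
  ann <- cylinder_annotation(2000, 400)  # unlabeled skeleton
  d <- compute_descriptors(compute_width_profile(ann))
  expect_true(is.na(d$head_diameter) && is.na(d$neck_diameter) &&
                is.na(d$neck_area) && is.na(d$cv_head))
  expect_false(is.na(d$spine_length) || is.na(d$spine_area) ||
                 is.na(d$cv_spine))
})

test_that("scaling outlines by c scales diameters and areas by c, CVs fixed", {
  set.seed(33)
  sp <- sample_spine(default_archetypes()[[2]])
  pr <- compute_width_profile(sp)
  c_fac <- 1.7
  # uniform scaling of the entire annotation (skeleton + outlines) scales
  # diameters by c, arc length by c, hence areas by c^2 and CVs not at all
  sk2 <- sp$skeleton
  sk2$nodes <- sk2$nodes * c_fac
  out2 <- lapply(sp$outlines, function(o)
    plane_outline(o$z * c_fac, o$vertices * c_fac))
  sp2 <- spine_annotation(sk2, out2, notes = sp$notes)
  pr2 <- compute_width_profile(sp2, step_nm = 20 * c_fac)
  expect_equal(pr2$d, pr$d * c_fac, tolerance = 1e-6)
  d1 <- compute_descriptors(pr)
  d2 <- compute_descriptors(pr2)
  expect_equal(d2$head_diameter, d1$head_diameter * c_fac, tolerance = 1e-6)
  expect_equal(d2$spine_area, d1$spine_area * c_fac^2, tolerance = 1e-6)
  expect_equal(d2$cv_spine, d1$cv_spine, tolerance = 1e-9)
})

test_that("disjoint neck+head regions covering all samples add up", {
  s <- seq(0, 2000, by = 20)
  set.seed(34)
  d <- 300 + 50 * sin(s / 200) + stats::rnorm(length(s), 0, 5)
  region <- ifelse(s <= 900, "neck", "head")
  pr <- structure(list(s = s, d = d, region = region, spine_id = "a"),
                  class = "width_profile")
  de <- compute_descriptors(pr)
  # additivity within one boundary sample (one 20 nm interval x local d)
  expect_lt(abs(de$neck_area + de$head_area - de$spine_area),
            20 * max(d))
})

test_that("incomplete spines and missing outlines raise contract errors", {
  ann <- cylinder_annotation(2000, 400)
  ann$complete <- FALSE
  expect_error(compute_width_profile(ann), "incomplete")

  # skeleton point outside its outline
  nodes <- cbind(c(0, 500, 1000), 0, 0)
  sk <- spine_skeleton(nodes, spine_id = "esc")
  small <- rbind(c(-20, -50), c(400, -50), c(400, 50), c(-20, 50))
  ann2 <- spine_annotation(sk, list(plane_outline(0, small)))
  expect_error(compute_width_profile(ann2), "outside its outline.*esc")
})

test_that("generator/measurement closure holds for all archetypes", {
  # noise-free spines measured end to end recover the archetype descriptors
  arch <- default_archetypes()
  set.seed(35)
  t <- seq(0, 1, length.out = 100)
  for (a in arch) {
    sp <- sample_spine(a, straight = TRUE, noise_cv = 0)
    de <- compute_descriptors(compute_width_profile(sp))
    L <- sp$notes$true_length
    neck_t <- t >= a$neck_span[1] & t <= a$neck_span[2]
    head_t <- t >= a$head_span[1]
    expect_equal(de$neck_diameter, min(a$template[neck_t]), tolerance = 0.05)
    expect_equal(de$head_diameter, max(a$template[head_t]), tolerance = 0.05)
    expect_equal(de$spine_length, L, tolerance = 0.01)
    expect_equal(de$spine_area, L * mean(a$template), tolerance = 0.05)
  }
})
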