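test_that("NML reader converts voxel coordinates to nm via the scale", {
  path <- withr::local_tempfile(fileext = ".nml")
  minimal_nml(path)
  res <- read_skeleton_nml(path)
  expect_equal(res$scale_nm, c(20, 20, 300))
  expect_length(res$skeletons, 1)
  sk <- res$skeletons[[1]]
  expect_equal(unname(sk$nodes[1, ]), c(0, 0, 0))
  expect_equal(unname(sk$nodes[2, ]), c(400, 0, 300))
  expect_equal(sk$spine_id, "s1")
})

test_that("NML write/read round trip preserves coordinates and labels", {
  set.seed(11)
  arch <- default_archetypes()
  skeletons <- lapply(1:10, function(i)
    sample_spine(arch[[((i - 1) %% 4) + 1]],
                 spine_id = paste0("s", i))$skeleton)
  path <- withr::local_tempfile(fileext = ".nml")
  write_skeleton_nml(skeletons, c(20, 20, 300), path)
  back <- read_skeleton_nml(path)
  expect_length(back$skeletons, 10)
  for (i in 1:10) {
    expect_equal(back$skeletons[[i]]$nodes, skeletons[[i]]$nodes,
                 tolerance = 1e-9)
    expect_identical(back$skeletons[[i]]$region_labels,
                     skeletons[[i]]$region_labels)
    expect_identical(back$skeletons[[i]]$spine_id, skeletons[[i]]$spine_id)
  }
})

test_that("NML with two trees yields two skeletons with ids preserved", {
  path <- withr::local_tempfile(fileext = ".nml")
  writeLines(c(
    '<things>',
    ' <parameters><scale x="20" y="20" z="300"/></parameters>',
    ' <thing id="1" name="n1/d1/spA"><nodes>',
    '  <node id="1" x="0" y="0" z="0"/><node id="2" x="5" y="0" z="0"/>',
    ' </nodes><edges><edge source="1" target="2"/></edges></thing>',
    ' <thing id="2" name="n1/d2/spB"><nodes>',
    '  <node id="1" x="1" y="1" z="1"/><node id="2" x="2" y="1" z="1"/>',
    ' </nodes><edges><edge source="1" target="2"/></edges>',
    '  <comments><comment node="2" content="head"/></comments></thing>',
    '</things>'), path)
  res <- read_skeleton_nml(path)
  expect_length(res$skeletons, 2)
  expect_identical(vapply(res$skeletons, function(s) s$spine_id, ""),
                   c("spA", "spB"))
  expect_identical(res$skeletons[[2]]$region_labels, c("unlabeled", "head"))
})

test_that("NML errors: missing scale names the file; orphan nodes listed", {
  path <- withr::local_tempfile(fileext = ".nml")
  writeLines(c('<things><thing id="1"><nodes>',
               '<node id="1" x="0" y="0" z="0"/></nodes></thing></things>'),
             path)
  expect_error(read_skeleton_nml(path), path, fixed = TRUE)

  path2 <- withr::local_tempfile(fileext = ".nml")
  writeLines(c(
    '<things><parameters><scale x="20" y="20" z="300"/></parameters>',
    '<thing id="1"><nodes>',
    '<node id="1" x="0" y="0" z="0"/><node id="2" x="1" y="0" z="0"/>',
    '<node id="3" x="2" y="0" z="0"/></nodes>',
    '<edges><edge source="1" target="2"/></edges></thing></things>'), path2)
  expect_error(read_skeleton_nml(path2), "path|orphan|connected")
})

test_that("annotation JSON round trip is lossless for a generated dataset", {
  ds <- sample_dataset(synth_config(default_dendrite_table(2, 25), seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations_json(ds, path)
  back <- read_annotations_json(path)
  expect_length(back$spines, 50)
  expect_equal(back$scale_nm, ds$scale_nm)
  for (i in seq_along(ds$spines)) {
    expect_equal(back$spines[[i]]$skeleton$nodes, ds$spines[[i]]$skeleton$nodes,
                 tolerance = 1e-9)
    expect_identical(back$spines[[i]]$skeleton$region_labels,
                     ds$spines[[i]]$skeleton$region_labels)
    expect_equal(length(back$spines[[i]]$outlines),
                 length(ds$spines[[i]]$outlines))
    expect_equal(back$spines[[i]]$outlines[[1]]$vertices,
                 ds$spines[[i]]$outlines[[1]]$vertices, tolerance = 1e-9)
    expect_equal(back$spines[[i]]$notes$true_class,
                 ds$spines[[i]]$notes$true_class)
  }
})

test_that("complete=false spines are loaded but flagged excluded", {
  set.seed(3)
  arch <- default_archetypes()
  ann <- sample_spine(arch[[1]])
  ann$complete <- FALSE
  ds <- neuron_dataset(list(ann))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations_json(ds, path)
  back <- read_annotations_json(path)
  expect_false(back$spines[[1]]$complete)
  expect_equal(measure_dataset(back)$n_excluded, 1)
})

test_that("validators reject constructed invariant violations", {
  # < 2 nodes
  expect_error(spine_skeleton(matrix(c(0, 0, 0), 1, 3)), ">= 2 nodes")
  # non-contiguous head labels
  expect_error(
    spine_skeleton(cbind(0:3 * 100, 0, 0),
                   c("unlabeled", "head", "neck", "head")),
    "contiguous|precede")
  # self-intersecting outline polygon
  bow <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(plane_outline(0, bow), "self-intersecting")
  # outline plane with no skeleton node
  sk <- spine_skeleton(cbind(c(0, 100), 0, 0), spine_id = "sX")
  sq <- rbind(c(-10, -10), c(110, -10), c(110, 10), c(-10, 10))
  expect_error(spine_annotation(sk, list(plane_outline(300, sq))),
               "no skeleton node.*sX")
  # duplicate spine ids
  a1 <- spine_annotation(sk, list(plane_outline(0, sq)))
  expect_error(neuron_dataset(list(a1, a1)), "duplicate spine ids")

  # property: random vertex-order mutations that break simplicity are caught
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(6:12, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    r <- stats::runif(k, 50, 120)
    v <- cbind(cos(ang) * r, sin(ang) * r)   # star-shaped: simple
    expect_true(spinemorph:::polygon_is_simple(v))
    vswap <- v[sample(k), , drop = FALSE]    # random order: usually not
    if (!spinemorph:::polygon_is_simple(vswap))
      expect_error(plane_outline(0, vswap), "self-intersecting")
  }
})

test_that("result tables have the contracted shape and are deterministic", {
  ds <- sample_dataset(synth_config(default_dendrite_table(1, 3), seed = 5))
  meas <- measure_dataset(ds)
  labels <- stats::setNames(rep(1L, 3), meas$descriptors$spine_id)
  stats_df <- data.frame(test = "x", comparison = "y", statistic = 1,
                         df = 1, p = 0.5, p_adjusted = 1)
  d1 <- withr::local_tempdir()
  files <- write_results_tables(ds, meas$descriptors, labels, stats_df, d1)
  desc <- utils::read.csv(files["descriptors"])
  expect_equal(nrow(desc), 3)
  expect_true(all(c("head_diameter", "neck_diameter", "head_neck_ratio",
                    "spine_length", "spine_area", "neck_area", "head_area",
                    "cv_spine", "cv_neck", "cv_head", "class") %in% names(desc)))

  # empty stats -> header only
  d2 <- withr::local_tempdir()
  files2 <- write_results_tables(ds, meas$descriptors, labels, NULL, d2)
  expect_equal(nrow(utils::read.csv(files2["stats"])), 0)

  # byte-identical on re-run
  d3 <- withr::local_tempdir()
  files3 <- write_results_tables(ds, meas$descriptors, labels, stats_df, d3)
  for (f in names(files))
    expect_identical(readLines(files[[f]]), readLines(files3[[f]]))

  # id mismatch errors
  bad <- labels
  names(bad)[1] <- "nonexistent"
  expect_error(write_results_tables(ds, meas$descriptors, bad, stats_df, d1),
               "mismatch")
})
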