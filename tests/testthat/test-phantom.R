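test_that("phantom generation is deterministic and passes volume validation", {
  cfg <- phantomConfig(gap = 2, angle = 40, jitterSd = 0.4, seed = 99)
  v1 <- generatePhantom(cfg)
  v2 <- generatePhantom(cfg)
  expect_identical(voxels(v1), voxels(v2))
  expect_true(methods::validObject(v1))

  cfg2 <- phantomConfig(gap = 2, angle = 40, jitterSd = 0.4, seed = 100)
  expect_false(identical(voxels(v1), voxels(generatePhantom(cfg2))))
})

test_that("touching phantoms realize the connection boundary exactly", {
  v <- generatePhantom(phantomConfig(gap = 0, angle = 0, seed = 1))
  expect_equal(indexValue(computePLD(v, q = 100)), 1.0)
  expect_equal(indexValue(computePLA(v)), 0.0)
  ## gap 0 forces an edge-adjacent pair in EVERY shared slice
  for (p in sliceSupport(v)) expect_equal(minSliceDistance(p), 1.0)
  ## and at oblique bearings too
  v2 <- generatePhantom(phantomConfig(gap = 0, angle = 55, seed = 1))
  for (p in sliceSupport(v2)) expect_equal(minSliceDistance(p), 1.0)
})

test_that("configured gap and angle are recovered by the indices", {
  for (g in c(2, 5, 10)) {
    v <- generatePhantom(phantomConfig(gap = g, angle = 30, seed = 5))
    expect_equal(indexValue(computePLD(v, q = 100)), g + 1, tolerance = 0.5 / (g + 1))
    ## against the all-pairs oracle, slice by slice
    for (p in sliceSupport(v))
      expect_equal(minSliceDistance(p), bruteMinDist(p$pv, p$la))
  }
  for (a in c(15, 45, 75)) {
    v <- generatePhantom(phantomConfig(gap = 3, angle = a, seed = 5))
    expect_lt(abs(indexValue(computePLA(v)) - a), 2)
  }
})

test_that("the confluent vein is a disjoint label that merges into PV by default", {
  v <- generatePhantom(phantomConfig(gap = 4, angle = 30, vein = TRUE, seed = 2))
  vox <- voxels(v)
  expect_true(any(vox == 3L))
  ## one label per voxel by construction; merge switch changes the PV mask
  pvMerged <- structureMask(v, "PV", mergeVein = TRUE)
  pvAlone <- structureMask(v, "PV", mergeVein = FALSE)
  expect_equal(sum(pvMerged), sum(pvAlone) + sum(vox == 3L))
  ## the vein must not touch the LA mask
  expect_false(any(structureMask(v, "VEIN") & structureMask(v, "LA")))
})

test_that("impossible geometry raises a configuration error naming the extent", {
  err <- tryCatch(
    generatePhantom(phantomConfig(shape = c(8L, 24L, 24L), gap = 10,
                                  angle = 0, seed = 1)),
    error = identity)
  expect_s3_class(err, "pvlaConfigError")
  expect_match(conditionMessage(err), "extent")
  expect_error(phantomConfig(sharedSlices = 20, shape = c(8L, 64L, 64L)),
               class = "pvlaConfigError")
  expect_error(phantomConfig(pvThickness = 13L, pvLength = 13L),
               class = "pvlaConfigError")
})

test_that("generateCohort is reproducible on disk and respects group geometry", {
  spec <- cohortSpec(nNormal = 3, nTapvc = 3, videosPerCase = 1,
                     shape = c(8L, 72L, 72L), sharedSlices = 4, seed = 77)
  d1 <- file.path(withr::local_tempdir(), "c1")
  d2 <- file.path(withr::local_tempdir(), "c2")
  r1 <- generateCohort(spec, outDir = d1)
  r2 <- generateCohort(spec, outDir = d2)
  expect_equal(nrow(r1$cohort), 6L)
  expect_identical(unname(tools::md5sum(file.path(d1, r1$cohort$volume_ref))),
                   unname(tools::md5sum(file.path(d2, r2$cohort$volume_ref))))

  ## normal-only cohorts sit exactly at the connection boundary
  normSpec <- cohortSpec(nNormal = 4, nTapvc = 1, videosPerCase = 1,
                         shape = c(8L, 72L, 72L), sharedSlices = 4, seed = 31)
  res <- generateCohort(normSpec)
  for (i in which(res$params$group == "normal"))
    expect_equal(indexValue(computePLD(res$volumes[[i]], q = 100)), 1.0)
  for (i in which(res$params$group == "TAPVC"))
    expect_gt(indexValue(computePLD(res$volumes[[i]], q = 100)), 1.0)
  ## round trip through mask_io validation
  tab <- loadCohort(file.path(d1, "cohort.csv"))
  back <- readLabelVolume(tab$volume_path[1], caseId = tab$case_id[1])
  expect_identical(voxels(back), voxels(r1$volumes[[1]]))
})

test_that("separated generating distributions yield perfect screening AUC", {
  spec <- cohortSpec(nNormal = 5, nTapvc = 5, videosPerCase = 1,
                     normalGap = list(dist = "const", value = 0),
                     tapvcGap = list(dist = "norm", mean = 6, sd = 1,
                                     min = 4, max = 9),
                     shape = c(8L, 72L, 72L), sharedSlices = 4, seed = 19)
  res <- generateCohort(spec)
  pld <- vapply(res$volumes, function(v) indexValue(computePLD(v)), numeric(1))
  tab <- data.frame(case_id = res$params$case_id, model_name = "ground_truth",
                    index_name = "PLD", value = pld, group = res$params$group)
  expect_equal(rocCurve(tab, "ground_truth", "PLD")$auc, 1.0)
})

test_that("perturbMask degrades one structure deterministically and safely", {
  v <- generatePhantom(phantomConfig(gap = 0, angle = 0, seed = 12))
  moved <- perturbMask(v, "translate", magnitude = 3, direction = c(0L, -1L))
  ## rigid 3 px shift of a solid bar: exact Hausdorff is exactly 3 and the
  ## robust variant never exceeds it; both match the brute-force oracle
  p <- structureMask(moved, "PV"); g <- structureMask(v, "PV")
  expect_equal(hausdorffDistance(moved, v, "PV"), 3.0)
  expect_equal(hd95(moved, v, "PV"), bruteHD95(p, g), tolerance = 1e-9)

  ## erosion beyond the bar thickness empties the structure
  expect_warning(gone <- perturbMask(v, "erode", magnitude = 3,
                                     structure = "PV"),
                 "emptied")
  expect_true(isTRUE(attr(gone, "emptyStructure")))

  expect_error(perturbMask(v, "translate", magnitude = 0),
               class = "pvlaPreconditionError")

  ## dilation never overwrites the other structure
  fat <- perturbMask(v, "dilate", magnitude = 2, structure = "PV")
  expect_identical(structureMask(fat, "LA"), structureMask(v, "LA"))
  expect_gt(sum(structureMask(fat, "PV")), sum(structureMask(v, "PV")))

  dropped <- perturbMask(v, "drop_slices", magnitude = 2, seed = 5,
                         structure = "PV")
  expect_equal(length(sliceSupport(dropped)), length(sliceSupport(v)) - 2L)
  expect_identical(voxels(perturbMask(v, "drop_slices", magnitude = 2,
                                      seed = 5, structure = "PV")),
                   voxels(dropped))
})

test_that("boundary jitter preserves exclusivity and leaves indices near the target", {
  cfg <- phantomConfig(gap = 5, angle = 30, jitterSd = 0.5, seed = 41)
  v <- generatePhantom(cfg)
  expect_true(methods::validObject(v))
  ## jittered but still measurable and in the right neighborhood
  expect_lt(abs(indexValue(computePLD(v)) - 6), 1.5)
})
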