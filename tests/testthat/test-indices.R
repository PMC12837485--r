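test_that("sliceSupport returns exactly the slices carrying both structures", {
  vox <- array(0L, dim = c(10L, 8L, 8L))
  vox[, 1, 1] <- 1L            # LA everywhere
  vox[4:8, 5, 5] <- 2L         # PV in slices 4..8
  sp <- sliceSupport(LabelVolume(vox))
  expect_equal(vapply(sp, function(p) p$k, numeric(1)), 4:8)

  onlyPV <- array(0L, dim = c(4L, 4L, 4L)); onlyPV[, 2, 2] <- 2L
  expect_length(sliceSupport(LabelVolume(onlyPV)), 0L)

  set.seed(5)
  rnd <- array(sample(0:2, 6 * 6 * 6, replace = TRUE, prob = c(.8, .1, .1)),
               dim = c(6L, 6L, 6L))
  sp2 <- sliceSupport(LabelVolume(rnd))
  expected <- which(vapply(1:6, function(k)
    any(rnd[k, , ] == 2L) && any(rnd[k, , ] == 1L), logical(1)))
  expect_equal(vapply(sp2, function(p) p$k, numeric(1)), as.numeric(expected))
})

test_that("minSliceDistance matches hand values and the all-pairs oracle", {
  v <- sliceVolume(pvPix = cbind(5, 5), laPix = cbind(5, 6))
  expect_equal(minSliceDistance(sliceSupport(v)[[1]]), 1.0)
  v2 <- sliceVolume(pvPix = cbind(1, 1), laPix = cbind(4, 5))
  expect_equal(minSliceDistance(sliceSupport(v2)[[1]]), 5.0)  # 3-4-5 triangle
  expect_error(minSliceDistance(list(pv = cbind(1, 1)[0, , drop = FALSE],
                                     la = cbind(1, 1))),
               class = "pvlaPreconditionError")
  set.seed(31)
  for (i in 1:25) {
    a <- randomBlob(50, start = c(10, 10))
    b <- randomBlob(50, start = c(30, 30))
    b <- b[!duplicated(rbind(a, b))[-seq_len(nrow(a))], , drop = FALSE]
    expect_equal(minSliceDistance(list(pv = a, la = b)), bruteMinDist(a, b))
  }
})

test_that("quantileSubset follows the linear-interpolation threshold rule", {
  expect_equal(sort(quantileSubset(c(3, 1, 4, 2), 100)$subset), c(1, 2, 3, 4))
  expect_equal(quantileSubset(c(7, 7, 7), 10)$subset, c(7, 7, 7))
  qs <- quantileSubset(c(1, 1, 1, 3), 75)
  expect_equal(qs$tQ, 1.5)           # hand-evaluated type-7 percentile
  expect_equal(qs$subset, c(1, 1, 1))
  expect_error(quantileSubset(numeric(0), 50), class = "pvlaPreconditionError")
  expect_error(quantileSubset(c(1, 2), 0), class = "pvlaValidationError")
  expect_error(quantileSubset(c(1, 2), 101), class = "pvlaValidationError")
  ## shrinking q never increases the mean of the retained subset
  set.seed(9)
  d <- runif(40, 1, 20)
  means <- vapply(c(100, 80, 60, 40, 20),
                  function(q) mean(quantileSubset(d, q)$subset), numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("computePLD: touching phantom gives exactly 1.00, separation adds up", {
  v <- generatePhantom(phantomConfig(gap = 0, angle = 0, seed = 3))
  res <- computePLD(v, q = 100)
  expect_equal(indexValue(res), 1.0)
  expect_equal(res@nUsed, nrow(sliceTable(res)))

  ## rigid 6 px in-plane translation away from touching: PLD = 6 + 1
  v6 <- perturbMask(v, "translate", magnitude = 6, direction = c(0L, -1L))
  expect_equal(indexValue(computePLD(v6, q = 100)), 7.0)

  onlyPV <- array(0L, dim = c(4L, 6L, 6L)); onlyPV[, 3, 3] <- 2L
  err <- tryCatch(computePLD(LabelVolume(onlyPV)), error = identity)
  expect_s3_class(err, "pvlaNoSharedSliceError")
  expect_match(conditionMessage(err), "LA: absent")
})

test_that("PLD is invariant under joint translation and depth reversal, and monotone in separation", {
  v <- generatePhantom(phantomConfig(gap = 2, angle = 20, seed = 8))
  base <- indexValue(computePLD(v))
  vox <- voxels(v)
  shifted <- array(0L, dim = dim(vox))
  shifted[, 3:dim(vox)[2], 4:dim(vox)[3]] <-
    vox[, 1:(dim(vox)[2] - 2), 1:(dim(vox)[3] - 3)]
  expect_equal(indexValue(computePLD(LabelVolume(shifted))), base)
  flipped <- vox[rev(seq_len(dim(vox)[1])), , ]
  expect_equal(indexValue(computePLD(LabelVolume(flipped))), base)

  touch <- generatePhantom(phantomConfig(gap = 0, angle = 0, seed = 8))
  plds <- vapply(c(1, 3, 5, 9), function(t)
    indexValue(computePLD(perturbMask(touch, "translate", magnitude = t,
                                      direction = c(0L, -1L)))), numeric(1))
  expect_true(all(diff(plds) > 0))
  expect_true(all(plds >= 1))
})

test_that("sliceCentroid is the coordinate mean", {
  expect_equal(sliceCentroid(cbind(1, 1)), c(row = 1, col = 1))
  expect_equal(sliceCentroid(rbind(c(1, 1), c(1, 3))), c(row = 1, col = 2))
  set.seed(12)
  b <- randomBlob(80)
  expect_equal(unname(sliceCentroid(b)), c(sum(b[, 1]) / 80, sum(b[, 2]) / 80))
  expect_error(sliceCentroid(cbind(1, 1)[0, , drop = FALSE]),
               class = "pvlaPreconditionError")
})

test_that("majorAxisDirection matches the eigen oracle and flags isotropy", {
  bar <- cbind(5, 1:9)                       # 1 x 9 horizontal bar
  ax <- majorAxisDirection(bar)
  expect_false(ax$degenerate)
  expect_equal(abs(ax$direction), c(0, 1))   # column direction, sign-free

  square <- as.matrix(expand.grid(1:5, 1:5)) # isotropic moments
  expect_true(majorAxisDirection(square)$degenerate)
  expect_true(majorAxisDirection(cbind(3, 3))$degenerate)

  set.seed(21)
  nChecked <- 0
  for (i in 1:40) {
    n <- 60
    pix <- unique(round(cbind(rnorm(n, 0, 6) , rnorm(n, 0, 2)) %*%
      matrix(c(cos(i), sin(i), -sin(i), cos(i)), 2)) + 30)
    if (nrow(pix) < 5) next
    ax <- majorAxisDirection(pix)
    ctr <- sweep(pix, 2, colMeans(pix))
    ev <- eigen(crossprod(ctr) / nrow(pix), symmetric = TRUE)
    if (ev$values[1] <= ev$values[2] * (1 + 1e-9)) {
      expect_true(ax$degenerate)
    } else {
      expect_false(ax$degenerate)
      expect_equal(abs(sum(ax$direction * ev$vectors[, 1])), 1,
                   tolerance = 1e-9)
      nChecked <- nChecked + 1
    }
  }
  expect_gte(nChecked, 30)
})

test_that("sliceAngle realizes the endpoints and folds obtuse angles", {
  bar <- barPixels(10, 6, thickness = 1, len = 9)  # axis along columns
  laRow <- rbind(c(20, 10), c(21, 10), c(20, 11), c(21, 11), c(20, 9), c(21, 9))
  ## LA centroid displaced purely along rows -> 90 degrees
  expect_equal(sliceAngle(list(pv = bar, la = laRow))$theta, 90)
  ## displaced purely along columns -> 0 degrees
  laCol <- cbind(10, 20:24)
  expect_equal(sliceAngle(list(pv = bar, la = laCol))$theta, 0)
  ## raw angle 135 folds to 45
  la45 <- cbind(10 + 5, 10 - 5)
  expect_equal(sliceAngle(list(pv = bar, la = la45))$theta, 45)
  ## degenerate PV and coincident centroids are flagged
  sq <- as.matrix(expand.grid(1:5, 1:5))
  expect_true(sliceAngle(list(pv = sq, la = cbind(10, 10)))$degenerate)
  ring <- rbind(c(9, 10), c(11, 10))  # centroid (10,10) = bar centroid
  expect_true(sliceAngle(list(pv = bar, la = ring))$degenerate)
})

test_that("computePLA averages per-slice folded angles and flags degeneracy", {
  ## 4 slices at 90 degrees + 4 slices at 0 degrees -> mean 45
  h <- 32; w <- 32
  vox <- array(0L, dim = c(8L, h, w))
  bar <- barPixels(10, 6, thickness = 1, len = 9)
  for (k in 1:4) {
    vox[cbind(k, bar[, 1], bar[, 2])] <- 2L
    vox[cbind(k, 20, 10)] <- 1L          # along rows: 90
  }
  for (k in 5:8) {
    vox[cbind(k, bar[, 1], bar[, 2])] <- 2L
    vox[cbind(k, 10, 24)] <- 1L          # along columns: 0
  }
  res <- computePLA(LabelVolume(vox))
  expect_equal(indexValue(res), 45)
  expect_equal(res@nUsed, 8L)

  ## isotropic PV (filled circle) in every slice: no measurable angle
  circ <- as.matrix(expand.grid(row = 1:21, col = 1:21))
  circ <- circ[(circ[, 1] - 11)^2 + (circ[, 2] - 11)^2 <= 25, ]
  vox2 <- array(0L, dim = c(3L, h, w))
  for (k in 1:3) {
    vox2[cbind(k, circ[, 1], circ[, 2])] <- 2L
    vox2[cbind(k, 28, 28)] <- 1L
  }
  expect_error(computePLA(LabelVolume(vox2)),
               class = "pvlaNoMeasurableAngleError")

  ## PLA invariant under 180-degree rotation of PV about its centroid
  v <- generatePhantom(phantomConfig(gap = 2, angle = 35, seed = 4))
  base <- indexValue(computePLA(v))
  vox3 <- voxels(v)
  for (k in seq_len(dim(vox3)[1])) {
    sl <- vox3[k, , ]
    pv <- which(sl == 2L, arr.ind = TRUE)
    if (!nrow(pv)) next
    ctr <- colMeans(pv)
    rot <- round(sweep(-sweep(pv, 2, ctr), 2, ctr, "+"))
    sl[pv] <- 0L; sl[rot] <- 2L
    vox3[k, , ] <- sl
  }
  expect_equal(indexValue(computePLA(LabelVolume(vox3))), base,
               tolerance = 1e-9)
})
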