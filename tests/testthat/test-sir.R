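test_that("boundary tracing enumerates face-boundary pixels in order", {
  # single pixel: below the component area filter
  roi <- matrix(FALSE, 8, 8); roi[4, 4] <- TRUE
  expect_length(traceBoundary(roi, minArea = 5L), 0)

  # full 3x3: all 8 perimeter pixels, center excluded
  roi <- matrix(FALSE, 7, 7); roi[3:5, 3:5] <- TRUE
  paths <- traceBoundary(roi, minArea = 5L)
  expect_length(paths, 1)
  pts <- paths[[1]]$points
  expect_equal(nrow(pts), 8)
  expect_false(any(pts[, 1] == 4 & pts[, 2] == 4))

  # 5x5: 16 boundary pixels (independent enumeration of pixels with a
  # face-neighbor outside)
  roi <- matrix(FALSE, 9, 9); roi[3:7, 3:7] <- TRUE
  pts <- traceBoundary(roi)[[1]]$points
  expected <- which(roi & !(rbind(FALSE, roi[-9, ]) & rbind(roi[-1, ], FALSE) &
                            cbind(FALSE, roi[, -9]) & cbind(roi[, -1], FALSE)),
                    arr.ind = TRUE)
  expect_equal(nrow(pts), nrow(expected))
  expect_setequal(paste(pts[, 1], pts[, 2]), paste(expected[, 1], expected[, 2]))

  # ordered: consecutive points 8-adjacent, path closed, deterministic,
  # starting at the top-left boundary pixel
  expect_equal(pts[1, ], c(3L, 3L))
  gaps <- pmax(abs(diff(pts[, 1])), abs(diff(pts[, 2])))
  expect_true(all(gaps == 1))
  expect_lte(max(abs(pts[1, ] - pts[nrow(pts), ])), 1)
  expect_identical(traceBoundary(roi)[[1]]$points, pts)

  # empty slice
  expect_length(traceBoundary(matrix(FALSE, 5, 5)), 0)
})

test_that("RP extraction pads the ROI bounding box and clips at slice edges", {
  noss <- matrix(runif(40 * 40), 40, 40)
  roi <- matrix(FALSE, 40, 40); roi[11:20, 15:26] <- TRUE  # 10 x 12 box
  rp <- extractRP(noss, roi, pad = 3L)
  expect_equal(dim(rp@intensities), c(16L, 18L))
  expect_equal(rp@origin, c(8L, 12L))
  rp5 <- extractRP(noss, roi, pad = 5L)
  expect_equal(dim(rp5@intensities), c(20L, 22L))

  roiEdge <- matrix(FALSE, 40, 40); roiEdge[1:6, 1:6] <- TRUE
  rpE <- extractRP(noss, roiEdge, pad = 3L)
  expect_equal(rpE@origin, c(1L, 1L))
  expect_equal(dim(rpE@intensities), c(9L, 9L))

  expect_error(extractRP(noss, matrix(FALSE, 40, 40)), "empty ROI")
})

test_that("RP standardization scales the valid maximum to 1", {
  v <- matrix(c(0.04, 0.02, 0.01, 0.03), 2, 2)
  rp <- new("RPImage", intensities = v, origin = c(1L, 1L),
            standardized = FALSE, degenerateFlag = FALSE)
  s <- standardizeRP(rp)
  expect_equal(s@intensities, v * 25)
  expect_equal(max(s@intensities), 1)
  expect_error(standardizeRP(s), "already standardized")

  z <- new("RPImage", intensities = matrix(0, 3, 3), origin = c(1L, 1L),
           standardized = FALSE, degenerateFlag = FALSE)
  sz <- standardizeRP(z)
  expect_true(sz@degenerateFlag)
  expect_equal(sz@intensities, matrix(0, 3, 3))

  # masked entries are ignored in the maximum
  vm <- matrix(c(0.5, NA, 0.25, 0.1), 2, 2)
  rm_ <- new("RPImage", intensities = vm, origin = c(1L, 1L),
             standardized = FALSE, degenerateFlag = FALSE)
  sm <- standardizeRP(rm_)
  expect_equal(sm@intensities[1, 1], 1)
  expect_true(is.na(sm@intensities[2, 1]))
})

test_that("patch selection escalates to 5x5 only below the threshold", {
  mkRP <- function(v) standardizeRP(new("RPImage", intensities = v,
    origin = c(1L, 1L), standardized = FALSE, degenerateFlag = FALSE))

  # |mean3 - I(a)| well above 0.065: keep 3x3
  v <- matrix(0.2, 9, 9); v[5, 5] <- 0.6; v[1, 1] <- 1
  p <- selectPatch(mkRP(v), c(5L, 5L))
  expect_equal(p@size, 3L)

  # mean equals the point: escalate
  v2 <- matrix(0.3, 9, 9); v2[1, 1] <- 1
  p2 <- selectPatch(mkRP(v2), c(5L, 5L))
  expect_equal(p2@size, 5L)
  expect_equal(dim(p2@values), c(5L, 5L))

  # uniform RP always escalates (mean equals center)
  p3 <- selectPatch(mkRP(matrix(0.4, 7, 7)), c(4L, 4L))
  expect_equal(p3@size, 5L)

  # edge replication at the RP corner keeps the patch complete
  v4 <- matrix(seq(0, 1, length.out = 25), 5, 5)
  p4 <- selectPatch(mkRP(v4), c(1L, 1L))
  expect_false(anyNA(p4@values))
  expect_equal(nrow(p4@values), p4@size)
  expect_error(selectPatch(mkRP(v4), c(0L, 3L)), "outside")
})

test_that("the three-condition decision function fires as specified", {
  params <- sirParams()
  mkPatch <- function(vals, size) {
    v <- matrix(vals, size, size)
    vv <- v[!is.na(v)]
    new("Patch", center = c(1, 1), size = as.integer(size), values = v,
        stats = c(min = min(vv), max = max(vv), mean = mean(vv)))
  }

  # Condition I: hyper-intense point
  p <- mkPatch(rep(0.5, 9), 3)
  r <- classifyPoint(0.90, p, rpMax = 1, rpMin = 0.05, params)
  expect_true(r$nonAdherent); expect_equal(r$condition, "I")

  # Condition II: point far from patch mean
  vals <- c(rep(0.15, 4), 0.60, rep(0.15, 4))
  p2 <- mkPatch(vals, 3)
  expect_equal(p2@stats[["mean"]], 0.20)
  r2 <- classifyPoint(0.60, p2, rpMax = 1, rpMin = 0, params)
  expect_true(r2$nonAdherent); expect_equal(r2$condition, "II")

  # Condition III: point matches the mean but the patch range is large
  vals3 <- c(rep(0.05, 4), rep(0.55, 4), rep(0.30, 17))
  p3 <- mkPatch(vals3, 5)
  expect_equal(p3@stats[["mean"]], 0.30)
  r3 <- classifyPoint(0.30, p3, rpMax = 1, rpMin = 0.05 / 1.2, params)
  expect_true(r3$nonAdherent); expect_equal(r3$condition, "III")

  # adherent: uniform patch, point inside the Condition I bounds
  p4 <- mkPatch(rep(0.40, 9), 3)
  r4 <- classifyPoint(0.40, p4, rpMax = 1, rpMin = 0.05, params)
  expect_false(r4$nonAdherent); expect_equal(r4$condition, "none")
})

test_that("adhesion percentages pool boundary counts across slices", {
  mkPoints <- function(nPerSlice, naPerSlice) {
    do.call(rbind, lapply(seq_along(nPerSlice), function(s) {
      n <- nPerSlice[s]
      data.frame(slice = s, row = seq_len(n), col = 1,
                 nonAdherent = seq_len(n) <= naPerSlice[s],
                 condition = ifelse(seq_len(n) <= naPerSlice[s], "II", "none"))
    }))
  }
  allNA <- mkPoints(8, 8)
  res <- adhesionPercentages(allNA)
  expect_equal(nonAdhesionPct(res), 100)
  expect_equal(adhesionPct(res), 0)

  res2 <- adhesionPercentages(mkPoints(8, 3))
  expect_equal(nonAdhesionPct(res2), 37.5)

  # pooled, not slice-averaged: (2 + 18) / (10 + 30) = 50%, not 40%
  res3 <- adhesionPercentages(mkPoints(c(10, 30), c(2, 18)))
  expect_equal(nonAdhesionPct(res3), 50)
  expect_equal(res3@perSlice$nNonAdherent, c(2, 18))
  expect_equal(nonAdhesionPct(res3) + adhesionPct(res3), 100)

  expect_error(adhesionPercentages(allNA[0, ]), "no analyzable boundary")
})

test_that("runSIR is deterministic, boundary-restricted and scale invariant", {
  set.seed(31)
  n <- 28L
  noss <- matrix(abs(rnorm(n * n, 1, 0.4)), n, n)
  roi <- matrix(FALSE, n, n); roi[8:20, 9:22] <- TRUE
  vol <- sliceAsVolume(noss, roi)

  r1 <- runSIR(vol$noss, vol$mask)
  r2 <- runSIR(vol$noss, vol$mask)
  expect_identical(pointLabels(r1), pointLabels(r2))

  # every labeled voxel is a boundary voxel of the ROI
  lv <- labelVolume(r1)
  bnd <- slipsir:::.faceBoundary2d(roi)
  expect_true(all(bnd[cbind(pointLabels(r1)$row, pointLabels(r1)$col)]))
  expect_true(all(lv[, , 1][!bnd] == 0))

  # invariant to global rescaling of the NOSS map
  vol10 <- sliceAsVolume(noss * 10, roi)
  r10 <- runSIR(vol10$noss, vol10$mask)
  expect_identical(pointLabels(r1)$nonAdherent, pointLabels(r10)$nonAdherent)
  expect_equal(nonAdhesionPct(r1), nonAdhesionPct(r10))

  # grid mismatch and empty-mask errors
  expect_error(runSIR(vol$noss, array(FALSE, c(3, 3, 3))), "differ")
  expect_error(runSIR(vol$noss, array(FALSE, dim(mapValues(vol$noss)))),
               "area filter")
})

test_that("raising the Condition I upper bound never adds Condition I points", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30L
    noss <- matrix(abs(rnorm(n * n, 1, 0.5)), n, n)
    roi <- randomBlobRoi(n)
    if (sum(roi) < 12) next
    vol <- sliceAsVolume(noss, roi)
    prevSet <- NULL
    for (cmax in c(0.5, 0.7, 0.9)) {
      res <- runSIR(vol$noss, vol$mask, sirParams(cond1MaxFrac = cmax,
                                                  cond1MinFrac = 0))
      pts <- pointLabels(res)
      setI <- paste(pts$row, pts$col)[pts$condition == "I"]
      if (!is.null(prevSet)) expect_true(all(setI %in% prevSet))
      prevSet <- setI
    }
  }
})

test_that("SIR labels match an exhaustive independent re-evaluation", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(20:32, 1)
    noss <- matrix(abs(rnorm(n * n, 1, 0.5)), n, n)
    noss[sample(n * n, 5)] <- NA  # a few masked pixels
    roi <- randomBlobRoi(n)
    if (sum(roi) < 12) next
    vol <- sliceAsVolume(noss, roi)
    res <- tryCatch(runSIR(vol$noss, vol$mask), error = function(e) NULL)
    if (is.null(res)) next
    got <- pointLabels(res)
    oracle <- sirSliceOracle(noss, roi)
    key <- function(d) paste(d$row, d$col)
    expect_setequal(key(got), key(oracle))
    m <- match(key(got), key(oracle))
    expect_identical(got$nonAdherent, oracle$nonAdherent[m])
    expect_identical(got$condition, oracle$condition[m])
  }
})
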