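# skeletonization, segment decomposition and the Vessel Connectivity metric

lineMask <- function(h = 11, w = 25, row = 6, cols = 3:23) {
  m <- matrix(0L, h, w); m[row, cols] <- 1L; m
}

test_that("thinning reduces a thick bar to a one-pixel-wide path", {
  m <- matrix(0L, 9, 27)
  m[4:6, 4:24] <- 1L  # 3 px thick, 21 px long
  sk <- skeletonizeMask(m)
  px <- skeletonPixels(sk)
  expect_true(nrow(px) >= 17 && nrow(px) <= 21)  # thinning trims the ends
  # one pixel wide: no pixel has more than 2 skeleton neighbours
  deg <- vesseltex:::.neighborCount8(sk@map) * sk@map
  expect_true(all(deg[sk@map == 1] <= 2))
  expect_true(all(sk@map[m == 0L] == 0L))  # inside the source mask
  expect_equal(componentCount8(sk@map), 1L)
})

test_that("thinning is idempotent and maps empty to empty", {
  set.seed(51)
  m <- matrix(0L, 32, 32)
  for (k in 1:4) {  # random blobs
    r <- sample(5:28, 1); c <- sample(5:28, 1)
    m[pmax(1, r - 2):pmin(32, r + 2), pmax(1, c - 3):pmin(32, c + 3)] <- 1L
  }
  sk <- skeletonizeMask(m)
  expect_identical(skeletonizeMask(sk@map)@map, sk@map)
  expect_equal(sum(skeletonizeMask(matrix(0L, 8, 8))@map), 0)
})

test_that("thinning preserves the connected-component count of blob masks", {
  set.seed(52)
  for (i in 1:10) {
    m <- matrix(0L, 40, 40)
    for (k in 1:sample(2:5, 1)) {
      r <- sample(4:36, 1); c <- sample(4:36, 1); s <- sample(2:4, 1)
      m[max(1, r - s):min(40, r + s), max(1, c - s):min(40, c + s)] <- 1L
    }
    expect_equal(componentCount8(skeletonizeMask(m)@map), componentCount8(m))
  }
})

test_that("segment decomposition handles lines, crossings and forks", {
  # straight line: one segment, two endpoints, no junctions
  segs <- decomposeSegments(skeletonizeMask(lineMask()))
  expect_equal(nSegments(segs), 1L)
  expect_equal(nrow(segs@endpoints), 2L)
  expect_equal(nrow(segs@junctions), 0L)
  # plus sign: four arm segments around a central junction cluster
  p <- matrix(0L, 11, 11); p[6, 2:10] <- 1L; p[2:10, 6] <- 1L
  segsP <- decomposeSegments(new("Skeleton", map = p))
  expect_equal(nSegments(segsP), 4L)
  expect_gte(nrow(segsP@junctions), 1L)
  expect_equal(componentCount8((function(x) {m <- matrix(0L, 11, 11); m[x] <- 1L; m})(segsP@junctions)), 1L)
  expect_equal(nrow(segsP@endpoints), 4L)
  # Y fork: three segments, three endpoints
  y <- matrix(0L, 13, 13)
  y[7:12, 7] <- 1L                       # stem
  for (k in 0:5) { y[6 - k, 7 - k] <- 1L; y[6 - k, 7 + k] <- 1L }
  segsY <- decomposeSegments(new("Skeleton", map = y))
  expect_equal(nSegments(segsY), 3L)
  expect_equal(nrow(segsY@endpoints), 3L)
  # every non-junction pixel belongs to exactly one segment
  covered <- do.call(rbind, segsY@paths)
  expect_equal(nrow(covered), sum(y) - nrow(segsY@junctions))
  expect_equal(nrow(unique(covered)), nrow(covered))
})

test_that("isolated cycles become one deterministic segment", {
  # diamond ring: every pixel has exactly two 8-neighbours
  r <- matrix(0L, 11, 11)
  for (dr in -3:3) {
    dc <- 3 - abs(dr)
    r[6 + dr, 6 - dc] <- 1L; r[6 + dr, 6 + dc] <- 1L
  }
  segs <- decomposeSegments(new("Skeleton", map = r))
  expect_equal(nSegments(segs), 1L)
  expect_equal(nrow(segs@paths[[1]]), sum(r))
  # rerun gives the identical ordering
  segs2 <- decomposeSegments(new("Skeleton", map = r))
  expect_identical(segs@paths, segs2@paths)
})

test_that("segment connectivity error reproduces the worked gap example", {
  gt <- lineMask()                       # 21 px line
  pred <- gt; pred[6, 11:15] <- 0L       # 5 interior pixels deleted
  skP <- skeletonizeMask(pred)
  segs <- decomposeSegments(skeletonizeMask(gt))
  expect_equal(nSegments(segs), 1L)
  path <- segs@paths[[1]]
  # matched distances ...,1,2 | 2,1,... and one unmatched interior point
  expect_equal(segmentCE(path, skP, rMatch = 2), 0.3 + 1, tolerance = 1e-12)
  # identical centerlines: zero error
  expect_equal(segmentCE(path, skeletonizeMask(gt)), 0)
  # empty prediction: total penalty equals the 20-step arc length
  expect_equal(segmentCE(path, skeletonizeMask(matrix(0L, 11, 25))), 20)
  # the full metric agrees
  expect_equal(vesselConnectivity(gt, pred)@vc, 1.3, tolerance = 1e-12)
})

test_that("VC is zero on identical masks and errors on empty ground truth", {
  ph <- makePhantom(3, size = 96, noiseSd = 0, depth = 3)
  expect_equal(vesselConnectivity(ph$fullMask, ph$fullMask)@vc, 0)
  expect_equal(vesselConnectivity(ph$fullMask, ph$fullMask)@matchedFraction, 1)
  expect_error(vesselConnectivity(matrix(0L, 8, 8), matrix(0L, 8, 8)),
               "undefined")
})

test_that("VC is bounded by total arc length over S plus the match radius", {
  set.seed(53)
  ph <- makePhantom(4, size = 96, noiseSd = 0, depth = 3)
  gt <- ph$fullMask
  segs <- decomposeSegments(skeletonizeMask(gt))
  bound <- sum(segs@lengths) / nSegments(segs) + 2
  for (i in 1:5) {
    pred <- matrix(rbinom(length(gt), 1, runif(1, 0, 0.3)), nrow(gt))
    expect_lte(vesselConnectivity(gt, pred)@vc, bound + 1e-9)
  }
  # empty prediction attains the arc-length part of the bound
  vc0 <- vesselConnectivity(gt, matrix(0L, nrow(gt), ncol(gt)))
  expect_equal(vc0@vc, mean(segs@lengths), tolerance = 1e-9)
  expect_equal(vc0@matchedFraction, 0)
})

test_that("VC agrees with the brute-force oracle on small random masks", {
  set.seed(54)
  for (i in 1:40) {
    gt <- matrix(0L, 7, 7)
    gt[sample(49, sample(3:12, 1))] <- 1L
    pred <- matrix(0L, 7, 7)
    pred[sample(49, sample(0:12, 1))] <- 1L
    expect_equal(vesselConnectivity(gt, pred)@vc, oracleVC(gt, pred),
                 tolerance = 1e-12)
  }
})

test_that("VC grows monotonically along nested gap degradations", {
  ph <- makePhantom(5, size = 128, noiseSd = 0)
  gt <- ph$fullMask
  segs <- decomposeSegments(skeletonizeMask(gt))
  path <- segs@paths[[which.max(segs@lengths)]]
  start <- floor(nrow(path) / 3)
  vcs <- vapply(c(0, 3, 6, 9, 12), function(L) {
    pred <- if (L == 0) gt else cutAlongPath(gt, path, start:(start + L - 1))
    vesselConnectivity(gt, pred)@vc
  }, numeric(1))
  expect_true(all(diff(vcs) >= -1e-9))
  expect_gt(vcs[length(vcs)], vcs[1])
})

test_that("deleting a whole branch raises VC by about its arc length share", {
  cfg <- phantomConfig(size = 128, depth = 1, noiseSd = 0)
  tree <- generateTree(cfg, 6)
  gt <- rasterizeMask(tree)
  # remove the second child branch entirely
  pred <- degradeMask(gt, list(list(op = "delete_branch", id = 3)),
                      seed = 1, tree = tree)
  expect_lt(sum(pred), sum(gt))
  vc <- vesselConnectivity(gt, pred)@vc
  expect_gt(vc, 0)
  segs <- decomposeSegments(skeletonizeMask(gt))
  expect_lte(vc, max(segs@lengths))
  expect_error(degradeMask(gt, list(list(op = "delete_branch", id = 99)),
                           seed = 1, tree = tree), "absent")
})
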