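test_that("labelComponents matches flood-fill at both connectivities", {
  set.seed(61)
  for (i in 1:20) {
    m <- randomMask(16, 16)
    for (conn in c(4, 8)) {
      a <- labelComponents(m, conn)
      b <- naiveLabel(m, conn)
      expect_equal(max(a), max(b))
      # same partition: labels agree up to renaming
      expect_equal(a > 0, b > 0)
      for (lb in seq_len(max(a)))
        expect_equal(length(unique(b[a == lb])), 1L)
    }
  }
})

test_that("traceBoundaries returns ordered closed outer boundaries", {
  m <- matrix(0L, 8, 8)
  m[3:5, 3:5] <- 1L
  tb <- traceBoundaries(m)
  expect_equal(max(tb$labels), 1L)
  b <- tb$boundaries[[1]]
  expect_equal(nrow(b), 8L)   # the 8 outer pixels of a filled 3x3 square
  expect_equal(b[1, ], c(row = 3, col = 3))
  # consecutive boundary pixels are 8-adjacent, and the loop closes
  steps <- rbind(diff(b), b[1, ] - b[nrow(b), ])
  expect_true(all(abs(steps) <= 1))
  # centre pixel is not on the boundary
  expect_false(any(b[, 1] == 4 & b[, 2] == 4))

  two <- matrix(0L, 12, 12)
  two[2:4, 2:4] <- 1L; two[8:10, 8:10] <- 1L
  tb2 <- traceBoundaries(two)
  expect_equal(max(tb2$labels), 2L)
  expect_length(tb2$boundaries, 2L)

  empty <- matrix(0L, 5, 5)
  tbe <- traceBoundaries(empty)
  expect_equal(max(tbe$labels), 0L)
  expect_length(tbe$boundaries, 0L)
})

test_that("dilateMask is the Euclidean-disc Minkowski dilation", {
  # single pixel, radius 1 -> plus shape
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  d <- dilateMask(m, 1)
  expect_equal(sum(d), 5L)
  expect_equal(d[2:4, 3], rep(1L, 3))
  expect_equal(d[3, 2:4], rep(1L, 3))

  empty <- matrix(0L, 6, 6)
  expect_equal(dilateMask(empty, 2), empty)

  set.seed(62)
  for (i in 1:10) {
    m <- randomMask(16, 16)
    d <- dilateMask(m, 2)
    expect_true(all(d[m == 1L] == 1L))   # extensivity
  }
})

test_that("removeSmallRegions keeps exactly the large components", {
  m <- matrix(0L, 12, 12)
  m[2:3, 2:3] <- 1L          # 4 px, will survive minArea 4
  m[6, 6:8] <- 1L            # 3 px, removed
  m[9:11, 2:11] <- 1L        # 30 px, survives
  out <- removeSmallRegions(m, 4)
  expect_equal(sum(out), 34L)
  expect_equal(out[6, 7], 0L)
  expect_equal(removeSmallRegions(m, 0), m)
  # result components are exactly the input components with area >= minArea
  expect_equal(max(labelComponents(out)), 2L)
  # idempotent
  expect_equal(removeSmallRegions(out, 4), out)
})

test_that("fillHoles fills enclosed background only", {
  ring <- matrix(0L, 12, 12)
  ring[4:8, 4] <- 1L; ring[4:8, 8] <- 1L; ring[4, 4:8] <- 1L; ring[8, 4:8] <- 1L
  filled <- fillHoles(ring)
  expect_equal(sum(filled), 25L)
  expect_true(all(filled[5:7, 5:7] == 1L))
  # solid regions unchanged; border-touching background never filled
  solid <- matrix(0L, 6, 6); solid[2:4, 2:4] <- 1L
  expect_equal(fillHoles(solid), solid)
  expect_equal(fillHoles(solid)[1, 1], 0L)
  # idempotent
  expect_equal(fillHoles(filled), filled)
})

test_that("morphology stages agree with brute-force oracles on random masks", {
  set.seed(63)
  for (i in 1:100) {
    m <- randomMask(32, 32)
    expect_identical(dilateMask(m, 2), naiveDilate(m, 2))
    expect_identical(fillHoles(m), naiveFillHoles(m))
    expect_identical(removeSmallRegions(m, 5), naiveRemoveSmall(m, 5))
  }
})

test_that("cannyEdges finds a thin closed contour of a solid region", {
  expect_equal(cannyEdges(matrix(0L, 20, 20)), matrix(0L, 20, 20))
  expect_equal(cannyEdges(matrix(1L, 20, 20)), matrix(0L, 20, 20))

  m <- matrix(0L, 64, 64)
  m[23:42, 23:42] <- 1L
  e <- cannyEdges(m)
  expect_gt(sum(e), 0)
  expect_equal(max(labelComponents(e, 8)), 1L)   # one closed loop
  # every edge pixel lies within 2 px of the square's perimeter
  per <- matrix(FALSE, 64, 64)
  per[23:42, c(23, 42)] <- TRUE; per[c(23, 42), 23:42] <- TRUE
  pi_ <- which(per, arr.ind = TRUE)
  ei <- which(e == 1L, arr.ind = TRUE)
  d2 <- outer(ei[, 1], pi_[, 1], "-")^2 + outer(ei[, 2], pi_[, 2], "-")^2
  expect_lte(max(apply(d2, 1, min)), 4)
})

test_that("selectRegion keeps the largest component with raster tie-break", {
  m <- matrix(0L, 10, 14)
  m[2:6, 2:5] <- 1L           # 20 px
  m[8:9, 8:11] <- 1L          # 8 px
  s <- selectRegion(m)
  expect_equal(sum(s), 20L)
  expect_equal(selectRegion(m, "all"), m)

  # equal sizes: the component whose first pixel comes first in raster order
  tie <- matrix(0L, 8, 8)
  tie[5:6, 2:3] <- 1L         # first pixel (5,2)
  tie[2:3, 6:7] <- 1L         # first pixel (2,6) -> earlier raster row
  s2 <- selectRegion(tie)
  expect_equal(sum(s2), 4L)
  expect_equal(s2[2, 6], 1L)
  expect_equal(s2[5, 2], 0L)

  expect_warning(s3 <- selectRegion(matrix(0L, 4, 4)), "empty")
  expect_equal(sum(s3), 0L)
})

test_that("postprocessMask recovers a solid blob and drops specks", {
  m <- matrix(0L, 96, 96)
  rows <- matrix(1:96, 96, 96); cols <- t(rows)
  disk <- (rows - 48)^2 + (cols - 48)^2 <= 20^2
  m[disk] <- 1L
  set.seed(64)
  for (s in 1:5) {             # scattered 2-px specks
    r0 <- sample(c(2:20, 76:94), 1); c0 <- sample(2:94, 1)
    m[r0, c0 + 0:1] <- 1L
  }
  out <- postprocessMask(m, morphControl())
  expect_equal(max(labelComponents(out)), 1L)
  truth <- matrix(as.integer(disk), 96, 96)
  # the recovered region is the blob grown by about the dilation radius,
  # so the overlap penalty scales with radius/r_blob
  expect_gte(diceCoef(out, truth), 0.85)
  expect_true(all(out[disk] == 1L))      # blob interior fully recovered
  # no speck survives: everything lies near the disk
  oi <- which(out == 1L, arr.ind = TRUE)
  expect_lte(max(sqrt((oi[, 1] - 48)^2 + (oi[, 2] - 48)^2)), 20 + 5)

  expect_warning(e <- postprocessMask(matrix(0L, 40, 40)), "empty")
  expect_equal(sum(e), 0L)
})
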