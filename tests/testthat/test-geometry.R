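test_that("grid construction matches the benchmark domain layout", {
  # 100 x 100 mm square, origin at the geometric center, 200 x 200 cells
  g <- buildGrid(gridSpec(200, 200, 0.5e-3, 0.5e-3,
                          origin = c(-0.05, -0.05)))
  expect_equal(g$dx, 0.5e-3)
  expect_equal(g$xc[1], -49.75e-3)
  expect_equal(g$yc[1], -49.75e-3)
  expect_equal(g$xc[200], 49.75e-3)
  # total volume = extent * depth
  g2 <- buildGrid(gridSpec(4, 4, 1, 1, depth = 2))
  expect_equal(sum(g2$V), 16 * 2)
  expect_error(gridSpec(3, 4, 1, 1), "nx and ny")
  expect_error(gridSpec(8, 8, -1, 1), "positive")
  expect_error(gridSpec(8, 8, 1, 1, depth = 0), "depth")
})

test_that("axisymmetric volumes and areas integrate the body of revolution", {
  g <- buildGrid(gridSpec(8, 4, 0.5, 1, coord = "axisymmetric"))
  # total volume = pi R^2 H
  expect_equal(sum(g$V), pi * 4^2 * 4, tolerance = 1e-12)
  # axial face areas equal the annulus areas
  expect_equal(sum(g$Ay[, 1]), pi * 4^2, tolerance = 1e-12)
  # radial face area at r: 2 pi r dz
  expect_equal(g$Ax[3, 1], 2 * pi * 1 * 1, tolerance = 1e-12)
})

test_that("rasterized solid area approximates shape area and refines", {
  for (n in c(64L, 128L)) {
    g <- smallGrid(n)
    r <- 10 * g$dx
    lay <- cellLayout(shapeCircle(c(0.5, 0.5), r))
    m <- rasterizeLayout(lay, g)
    est <- sum(m$solid) * g$dx * g$dy
    expect_lt(abs(est - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("rasterization agrees with a brute-force point-in-shape oracle", {
  g <- smallGrid(40L)
  lay <- cellLayout(shapeCircle(c(0.3, 0.3), 0.12),
                    list(list(center = c(0.75, 0.7), radius = 0.1,
                              type = "macrophage")))
  m <- rasterizeLayout(lay, g)
  oracle <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    x <- g$xc[i]; y <- g$yc[j]
    oracle[i, j] <- (x - 0.3)^2 + (y - 0.3)^2 <= 0.12^2 ||
      (x - 0.75)^2 + (y - 0.7)^2 <= 0.1^2
  }
  expect_identical(m$solid, oracle)
  # two disjoint circles: solid count is the sum of individual counts
  m1 <- rasterizeLayout(cellLayout(shapeCircle(c(0.3, 0.3), 0.12)), g)
  m2 <- rasterizeLayout(cellLayout(shapeCircle(c(0.75, 0.7), 0.1)), g)
  expect_equal(sum(m$solid), sum(m1$solid) + sum(m2$solid))
})

test_that("empty layouts and out-of-domain shapes are handled", {
  g <- smallGrid(8L)
  m <- rasterizeLayout(NULL, g)
  expect_true(all(!m$solid))
  expect_equal(sum(m$source_fx) + sum(m$source_fy), 0)
  bad <- cellLayout(shapeCircle(c(0.95, 0.5), 0.2))
  expect_error(rasterizeLayout(bad, g), "outside")
})

test_that("source faces separate fluid from tumor cells only", {
  g <- smallGrid(32L)
  lay <- cellLayout(shapeCircle(c(0.5, 0.5), 0.2),
                    list(list(center = c(0.15, 0.15), radius = 0.08,
                              type = "tcell")))
  m <- rasterizeLayout(lay, g)
  expect_gt(sum(m$source_fx) + sum(m$source_fy), 0)
  # every flagged x-face has one fluid and one tumor neighbor
  w <- which(m$source_fx, arr.ind = TRUE)
  for (r in seq_len(nrow(w))) {
    fi <- w[r, 1]; j <- w[r, 2]
    pair <- c(m$label[fi - 1, j], m$label[fi, j])
    expect_true(setequal(sort(pair), c(0L, 1L)))
  }
})

test_that("TME layout generation is reproducible and stage-scaled", {
  l1 <- generateTmeLayout("early", 4, 5, seed = 11)
  l2 <- generateTmeLayout("early", 4, 5, seed = 11)
  expect_identical(l1, l2)
  l3 <- generateTmeLayout("early", 4, 5, seed = 12)
  expect_false(identical(l1, l3))
  late <- generateTmeLayout("late", 4, 5, seed = 11)
  expect_equal((late$tumor$radius / l1$tumor$radius)^2, 1.8^2,
               tolerance = 1e-12)
  expect_gt(late$tumor$radius, l1$tumor$radius)
  # tumor-only layout is valid
  l0 <- generateTmeLayout("early", 0, 0, seed = 1)
  expect_length(l0$immune, 0)
  # generation does not disturb the global RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generateTmeLayout("early", 2, 2, seed = 5))
  expect_identical(runif(1), a)
})
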