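test_that("Reynolds number is rho U L / mu and scales linearly", {
  pr <- fluidProps(1000, 1e-3)
  expect_equal(reynoldsNumber(pr, 0.75e-6, 1e-4), 7.5e-5)
  expect_equal(reynoldsNumber(pr, 0, 1e-4), 0)
  expect_equal(reynoldsNumber(pr, 0.75e-6, 2e-4),
               2 * reynoldsNumber(pr, 0.75e-6, 1e-4))
  expect_error(fluidProps(-1, 1), "positive")
})

test_that("channel flow develops the plane-Poiseuille profile", {
  g <- buildGrid(gridSpec(192L, 64L, 1 / 64, 1 / 64))
  m <- emptyMask(g)
  fl <- solveFlow(g, m, fluidProps(), flowBCs(0.75e-6, lateral = "noslip"))
  prof <- fl$uf[96, ]
  expect_equal(max(prof) / mean(prof), 1.5, tolerance = 0.01)
  expect_lt(fl$div_rel, 1e-8)
  expect_equal(fl$influx, fl$outflux, tolerance = 1e-12 * abs(fl$influx))
  # parabola shape: compare with U(y) = 6 Umean y(1-y)/H^2
  yc <- g$yc
  exact <- 6 * 0.75e-6 * yc * (1 - yc)
  expect_lt(max(abs(prof - exact)) / max(exact), 0.01)
})

test_that("zero inlet velocity yields a quiescent field at reference pressure", {
  g <- smallGrid(16L)
  m <- emptyMask(g)
  fl <- solveFlow(g, m, fluidProps(), flowBCs(0, outlet_pressure = 2.5))
  expect_equal(max(abs(fl$uf)), 0)
  expect_equal(max(abs(fl$vf)), 0)
  expect_equal(unname(fl$p[!m$solid]), rep(2.5, sum(!m$solid)))
})

test_that("an obstacle increases the inlet-outlet pressure drop", {
  g <- smallGrid(48L)
  m0 <- emptyMask(g)
  lay <- cellLayout(shapeCircle(c(0.5, 0.5), 0.15))
  m1 <- rasterizeLayout(lay, g)
  bcs <- flowBCs(1e-6, lateral = "slip")
  f0 <- solveFlow(g, m0, fluidProps(), bcs)
  f1 <- solveFlow(g, m1, fluidProps(), bcs)
  dp0 <- mean(f0$p[1, ]) - mean(f0$p[48, ])
  dp1 <- mean(f1$p[1, !m1$solid[1, ]]) - mean(f1$p[48, !m1$solid[48, ]])
  expect_gt(dp1, dp0)
  # and enlarging the obstacle increases it further
  m2 <- rasterizeLayout(cellLayout(shapeCircle(c(0.5, 0.5), 0.25)), g)
  f2 <- solveFlow(g, m2, fluidProps(), bcs)
  dp2 <- mean(f2$p[1, ]) - mean(f2$p[48, ])
  expect_gt(dp2, dp1)
  # no-slip on the obstacle: velocities on solid faces vanish
  expect_equal(max(abs(f1$uf[2:48, ][m1$solid[1:47, ] | m1$solid[2:48, ]])), 0)
})

test_that("Stokes solutions scale linearly with the inlet speed", {
  g <- smallGrid(32L)
  m <- rasterizeLayout(cellLayout(shapeCircle(c(0.45, 0.55), 0.12)), g)
  f1 <- solveFlow(g, m, fluidProps(), flowBCs(1e-6))
  f2 <- solveFlow(g, m, fluidProps(), flowBCs(2e-6))
  expect_equal(f2$uf, 2 * f1$uf, tolerance = 1e-9)
  expect_equal(f2$vf, 2 * f1$vf, tolerance = 1e-9)
})

test_that("the inertial term is negligible at interstitial Reynolds numbers", {
  # tissue-scale domain (400 um) at 1 um/s: Re ~ 4e-4
  L <- 400e-6
  g <- smallGrid(24L, L = L)
  m <- rasterizeLayout(cellLayout(shapeCircle(c(0.5, 0.5) * L, 0.15 * L)), g)
  st <- solveFlow(g, m, fluidProps(), flowBCs(1e-6), inertia = FALSE)
  ns <- solveFlow(g, m, fluidProps(), flowBCs(1e-6), inertia = TRUE)
  rel <- function(a, b) max(abs(a$uf - b$uf)) / max(abs(a$uf))
  expect_lt(rel(st, ns), 1e-3)
  # and the difference shrinks with the Reynolds number (slower inlet)
  st2 <- solveFlow(g, m, fluidProps(), flowBCs(1e-8), inertia = FALSE)
  ns2 <- solveFlow(g, m, fluidProps(), flowBCs(1e-8), inertia = TRUE)
  expect_lt(rel(st2, ns2), rel(st, ns))
})

test_that("blocked geometries raise connectivity errors", {
  g <- smallGrid(16L)
  m <- emptyMask(g)
  m$solid[8, ] <- TRUE   # wall across the whole domain
  expect_error(solveFlow(g, m, fluidProps(), flowBCs(1e-6)), "connected")
})

test_that("streamlines follow the flow and avoid solids", {
  g <- smallGrid(32L)
  m <- emptyMask(g)
  vel <- uniformVelocity(g, u = 1e-6)
  fl <- list(uf = vel$uf, vf = vel$vf)
  s <- computeStreamlines(g, fl, m, cbind(0.05, c(0.3, 0.7)))
  for (pl in s) {
    expect_lt(diff(range(pl[, 2])), 1e-9)       # straight horizontal
    expect_gt(nrow(pl), 10)
  }
  # flow past a disk: no polyline point inside the solid
  md <- rasterizeLayout(cellLayout(shapeCircle(c(0.5, 0.5), 0.15)), g)
  fd <- solveFlow(g, md, fluidProps(), flowBCs(1e-6))
  sd <- computeStreamlines(g, fd, md, cbind(0.03, seq(0.2, 0.8, by = 0.15)))
  for (pl in sd) {
    ii <- pmin(32L, pmax(1L, 1L + floor(pl[, 1] / g$dx)))
    jj <- pmin(32L, pmax(1L, 1L + floor(pl[, 2] / g$dy)))
    expect_false(any(md$solid[cbind(ii, jj)]))
  }
  # a seed inside the solid is skipped with a warning
  expect_warning(computeStreamlines(g, fd, md, cbind(0.5, 0.5)), "skipped")
  # tangency: segments align with the local velocity to within 5 degrees
  pl <- sd[[2]]
  if (nrow(pl) > 5) {
    for (r in seq(2, nrow(pl) - 1, length.out = 4)) {
      r <- round(r)
      seg <- pl[r + 1, ] - pl[r, ]
      u <- interpVelocity(g, fd, pl[r, 1], pl[r, 2])
      ang <- acos(sum(seg * u) / sqrt(sum(seg^2) * sum(u^2))) * 180 / pi
      expect_lt(ang, 5)
    }
  }
})
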