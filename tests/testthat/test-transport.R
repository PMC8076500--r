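test_that("face reconstruction matches the scheme definitions", {
  # uniform stencil: every scheme returns the common value
  for (sch in c("upwind1", "upwind2", "quick", "muscl"))
    expect_equal(faceValue(7, 7, 7, sch), 7)
  # linear data (1, 2, 3): QUICK quadratic reconstruction is exact: 2.5
  expect_equal(faceValue(1, 2, 3, "quick"), 2.5)
  expect_equal(faceValue(1, 2, 3, "upwind2"), 2.5)
  expect_equal(faceValue(1, 2, 3, "upwind1"), 2)
  expect_equal(faceValue(1, 2, 3, "muscl"), 2.5)
  # local extremum: MUSCL face value bounded by neighbor cell values
  for (st in list(c(0, 5, 1), c(4, 0, 3), c(-2, 7, 7))) {
    fv <- faceValue(st[1], st[2], st[3], "muscl")
    expect_gte(fv, min(st[2], st[3]) - 1e-14)
    expect_lte(fv, max(st[2], st[3]) + 1e-14)
    fv <- faceValue(st[1], st[2], st[3], "muscl", "vanleer")
    expect_gte(fv, min(st[2], st[3]) - 1e-14)
    expect_lte(fv, max(st[2], st[3]) + 1e-14)
  }
  expect_error(transportParams(1e-9, scheme = "cubic"))
  expect_error(transportParams(-1), "positive")
})

test_that("uniform fields are preserved under divergence-free advection", {
  g <- centeredGrid(24L)
  m <- emptyMask(g)
  # shear velocity (divergence-free: d(U + lambda y)/dx = 0); inflow and
  # outflow carry the same constant value as the interior
  uf <- matrix(1 + rep(g$yc, each = g$nx + 1), g$nx + 1, g$ny)
  vel <- list(uf = uf, vf = matrix(0, g$nx, g$ny + 1))
  bc <- transportBC(left = bcSide("dirichlet", 3.5),
                    right = bcSide("dirichlet", 3.5))
  for (sch in c("upwind1", "upwind2", "quick", "muscl")) {
    tp <- transportParams(1e-30, scheme = sch)
    prob <- makeTransportProblem(g, m, vel, tp, bc = bc, dt = 0.01)
    c0 <- matrix(3.5, g$nx, g$ny)
    h <- runTransport(prob, c0, 0, 0.1)
    expect_lt(max(abs(h$final - 3.5)), 1e-12)
  }
})

test_that("a single-cell source injects exactly S dt of mass per step", {
  g <- smallGrid(12L)
  m <- emptyMask(g)
  cells <- matrix(FALSE, 12, 12); cells[5, 7] <- TRUE
  S <- 3.25
  tp <- transportParams(1e-3, scheme = "upwind1")
  prob <- makeTransportProblem(g, m, NULL, tp,
                               sources = sourceSpec(S, cells = cells),
                               dt = 0.5)
  st <- stepTransport(prob, matrix(0, 12, 12), 0)
  expect_equal(totalMass(st$c, g, m), S * 0.5, tolerance = 1e-14)
})

test_that("first-order upwind translates a top-hat exactly at unit CFL", {
  n <- 32L
  g <- buildGrid(gridSpec(n, 4L, 1 / n, 1 / n))
  m <- emptyMask(g)
  u <- 1
  dt <- g$dx / u  # CFL = 1
  vel <- uniformVelocity(g, u = u)
  tp <- transportParams(1e-30, scheme = "upwind1")
  bc <- transportBC(left = bcSide("dirichlet", 0), right = bcSide("outflow"))
  prob <- makeTransportProblem(g, m, vel, tp, bc = bc, dt = dt)
  c0 <- matrix(0, n, 4); c0[8:12, ] <- 1
  st <- list(c = c0, t = 0)
  for (k in 1:5) st <- stepTransport(prob, st$c, st$t)
  expected <- matrix(0, n, 4); expected[13:17, ] <- 1
  expect_equal(st$c, expected, tolerance = 1e-12)
})

test_that("closed-domain mass grows by exactly the injected source", {
  g <- smallGrid(16L)
  m <- emptyMask(g)
  fy <- matrix(FALSE, 16, 17); fy[, 1] <- TRUE
  S <- 2.0
  for (diff in c("implicit", "explicit")) {
    dt <- if (diff == "explicit") 5e-4 else 0.05
    tp <- transportParams(0.05, scheme = "upwind1", diffusion = diff)
    prob <- makeTransportProblem(g, m, NULL, tp,
                                 sources = sourceSpec(S, faces = list(fy = fy)),
                                 dt = dt)
    h <- runTransport(prob, 0, 0, dt * 40)
    expect_equal(h$mass[40, 1], S * dt * 40, tolerance = 1e-10)
    # every intermediate checkpoint too
    expect_equal(h$mass[, 1], S * seq(dt, by = dt, length.out = 40) * 1,
                 tolerance = 1e-10)
  }
})

test_that("pure diffusion spreads a Gaussian with the closed-form variance", {
  g <- centeredGrid(64L)
  m <- emptyMask(g)
  s0 <- 0.06; gamma <- 1e-3; Tend <- 10
  tp <- transportParams(gamma, scheme = "upwind1")
  prob <- makeTransportProblem(g, m, NULL, tp, dt = 0.1)
  c0 <- gaussianField(g, s0)
  h <- runTransport(prob, c0, 0, Tend)
  X <- matrix(g$xc, 64, 64)
  varx <- sum(h$final * X^2 * g$V) / sum(h$final * g$V)
  expect_equal(varx, s0^2 + 2 * gamma * Tend, tolerance = 0.01)
})

test_that("solutions scale linearly with the source strength", {
  g <- smallGrid(20L)
  lay <- cellLayout(shapeCircle(c(0.5, 0.5), 0.15))
  m <- rasterizeLayout(lay, g)
  vel <- uniformVelocity(g, u = 0.02)
  tp <- transportParams(1e-3, scheme = "quick")
  bc <- transportBC(left = bcSide("dirichlet", 0), right = bcSide("dirichlet", 0))
  mk <- function(S) {
    src <- sourceSpec(S, faces = list(fx = m$source_fx, fy = m$source_fy))
    prob <- makeTransportProblem(g, m, vel, tp, sources = src, bc = bc,
                                 dt = 0.2)
    runTransport(prob, 0, 0, 20)$final
  }
  c1 <- mk(1.0); c2 <- mk(2.0)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("first-order upwind creates no new extrema", {
  # closed recirculating vortex from a streamfunction: exactly
  # divergence-free discretely, zero normal velocity at the walls
  n <- 32L
  g <- smallGrid(n)
  m <- emptyMask(g)
  psi <- outer(g$xf, g$yf, function(x, y) 0.02 * sin(pi * x) * sin(pi * y))
  uf <- (psi[, -1] - psi[, -(n + 1)]) / g$dy          # u = d(psi)/dy
  vf <- -(psi[-1, ] - psi[-(n + 1), ]) / g$dx         # v = -d(psi)/dx
  div <- (uf[2:(n + 1), ] - uf[1:n, ]) / g$dx +
         (vf[, 2:(n + 1)] - vf[, 1:n]) / g$dy
  expect_lt(max(abs(div)), 1e-12)
  tp <- transportParams(1e-4, scheme = "upwind1")
  prob <- makeTransportProblem(g, m, list(uf = uf, vf = vf), tp, dt = 0.05)
  set.seed(4)
  c0 <- matrix(runif(n * n), n, n)
  h <- runTransport(prob, c0, 0, 2.5)
  expect_gte(min(h$final), min(c0) - 1e-12)
  expect_lte(max(h$final), max(c0) + 1e-12)
})

test_that("totalMass equals a brute-force sum and explicit stability is policed", {
  g <- buildGrid(gridSpec(10, 5, 0.2, 0.3, depth = 2))
  set.seed(2)
  cc <- matrix(rexp(50), 10, 5)
  acc <- 0
  for (i in 1:10) for (j in 1:5) acc <- acc + cc[i, j] * 0.2 * 0.3 * 2
  expect_equal(totalMass(cc, g), acc)
  expect_equal(totalMass(matrix(0, 10, 5), g), 0)
  # c = 1 over 10 cells of volume 2 (zero elsewhere) -> 20
  g1 <- buildGrid(gridSpec(10, 4, 1, 2))
  c1 <- matrix(0, 10, 4); c1[, 2] <- 1
  expect_equal(totalMass(c1, g1), 20)
  # explicit integrator rejects an unstable dt
  m <- emptyMask(g)
  tp <- transportParams(1.0, scheme = "upwind1", diffusion = "explicit")
  expect_error(makeTransportProblem(g, m, NULL, tp, dt = 10), "unstable")
})

test_that("multi-species fields advance independently with their own gamma", {
  g <- smallGrid(16L)
  m <- emptyMask(g)
  tp <- transportParams(c(1e-3, 5e-3), scheme = "upwind1")
  prob <- makeTransportProblem(g, m, NULL, tp, dt = 0.1)
  c0 <- gaussianField(g, 0.05)
  c0 <- list(c0, c0)
  # shift to center of the unit square
  h <- runTransport(prob, lapply(c0, function(x) x), 0, 2)
  m1 <- totalMass(h$final[[1]], g); m2 <- totalMass(h$final[[2]], g)
  expect_equal(m1, m2, tolerance = 1e-10)
  # faster-diffusing species has the lower peak
  expect_gt(max(h$final[[1]]), max(h$final[[2]]))
})
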