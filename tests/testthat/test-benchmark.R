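test_that("the analytic shear-plume field has the closed-form peak and symmetry", {
  # isotropic limit (lambda = 0, U = 0): peak = M / (4 pi D t)
  p0 <- shearBenchmarkParams(U = 0, lambda = 0)
  expect_equal(analyticGaussianShear(0, 0, 60, p0), 1 / (4 * pi * 1e-8 * 60),
               tolerance = 1e-12)
  expect_equal(analyticGaussianShear(0, 0, 60, p0), 132629.1, tolerance = 1e-6)
  # table parameters at t = 60 s: the peak sits at the advected center
  # (U t, 0) and is reduced by sqrt(1 + (lambda t)^2/12)
  pt <- shearBenchmarkParams()
  s <- sqrt(1 + (5e-4 * 60)^2 / 12)
  expect_equal(analyticGaussianShear(pt$U * 60, 0, 60, pt),
               1 / (4 * pi * 1e-8 * 60) / s, tolerance = 1e-12)
  expect_equal(analyticGaussianShear(pt$U * 60, 0, 60, pt), 132624.2,
               tolerance = 1e-6)
  # near the origin the value is lower by the advective offset factor
  expect_lt(analyticGaussianShear(0, 0, 60, pt),
            analyticGaussianShear(pt$U * 60, 0, 60, pt))
  # lambda = 0: symmetry about the advected center, c(x,y) = c(2Ut - x, -y)
  pu <- shearBenchmarkParams(lambda = 0)
  x <- c(1e-3, 3e-3, -2e-3); y <- c(0.5e-3, -1e-3, 2e-3); t <- 200
  expect_equal(analyticGaussianShear(x, y, t, pu),
               analyticGaussianShear(2 * pu$U * t - x, -y, t, pu))
  expect_error(analyticGaussianShear(0, 0, -1, pt), "positive")
  expect_error(shearBenchmarkParams(t_init = 0), "t_init")
})

test_that("the analytic field integrates to mass M at any time (quadrature)", {
  pt <- shearBenchmarkParams()
  for (t in c(60, 600, 2760)) {
    # midpoint quadrature on a fine grid over an extended box (at late
    # times a ~1e-4 tail of the sheared plume leaves the 100 mm domain)
    n <- 900
    W <- 3 * pt$L
    h <- W / n
    xs <- seq(-W / 2 + h / 2, W / 2 - h / 2, length.out = n)
    X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
    mass <- sum(analyticGaussianShear(X, Y, t, pt)) * h^2
    expect_equal(mass, pt$M, tolerance = 1e-6)
  }
})

test_that("initialization from the exact solution is faithful", {
  pt <- shearBenchmarkParams()
  g <- benchmarkGrid(200L, pt)
  c0 <- initFromAnalytic(g, pt)
  expect_equal(totalMass(c0, g), pt$M * g$depth, tolerance = 5e-3)
  # peak cell contains the origin: advected distance U t_init = 0.3 mm < dx
  pk <- which(c0 == max(c0), arr.ind = TRUE)
  expect_lt(abs(g$xc[pk[1]]), g$dx)
  expect_lt(abs(g$yc[pk[2]]), g$dy)
  # linear in M
  p2 <- pt; p2$M <- 2
  expect_equal(initFromAnalytic(g, p2), 2 * c0)
})

test_that("the imposed shear velocity is discretely divergence-free", {
  pt <- shearBenchmarkParams()
  g <- benchmarkGrid(64L, pt)
  vel <- exotran:::shearVelocity(g, pt)
  div <- (vel$uf[2:65, ] - vel$uf[1:64, ]) / g$dx +
         (vel$vf[, 2:65] - vel$vf[, 1:64]) / g$dy
  expect_equal(max(abs(div)), 0)
})

test_that("a coarse benchmark run beats first-order upwind with QUICK", {
  # smoke-scale verification (the acceptance suite runs the full grid)
  r1 <- runBenchmark(64L, "upwind1")
  rq <- runBenchmark(64L, "quick")
  expect_lt(rq$l2, r1$l2)
  expect_true(all(is.finite(rq$field)))
  # analytic peak drift over 45 min along y = 0: U * (t_end - t_init)
  pt <- shearBenchmarkParams()
  drift <- pt$U * (pt$t_end - pt$t_init)
  expect_equal(drift, 13.5e-3)
  pk <- which.max(rq$profiles$horizontal$analytic)
  expect_lt(abs(rq$profiles$horizontal$x_m[pk] - pt$U * pt$t_end),
            2 * rq$grid$dx)
})

test_that("lambda = 0 reduces to a translating heat kernel", {
  p0 <- shearBenchmarkParams(lambda = 0)
  r <- runBenchmark(128L, "quick", params = p0)
  expect_lt(r$linf_rel, 0.01)
})

test_that("the PDE oracle prefers the standard sheared-center sign", {
  a <- auditSignVariant(nx = 64L, scheme = "quick")
  expect_identical(a$best, "standard")
  expect_lt(a$l2[["standard"]] * 5, a$l2[["as_printed"]])
  # and the shipped default matches the oracle choice
  expect_identical(shearBenchmarkParams()$variant, "standard")
})

test_that("errors vanish under simultaneous grid and step refinement", {
  p <- shearBenchmarkParams()
  e <- sapply(c(50L, 100L, 200L), function(nx)
    runBenchmark(nx, "quick", params = p)$l2)
  expect_true(all(diff(e) < 0))
})
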