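test_that("release rates convert to total rates and fluxes correctly", {
  # NF: 515.3 /h per 1e5 cells x 3.6e6 cells = 515.3 * 36 per hour
  nf <- releaseFlux(3.6e6, 515.3, pi * 17.4e-3^2)
  expect_equal(nf$total_rate_per_h, 515.3 * 36)
  expect_equal(nf$total_rate, 515.3 * 36 / 3600)
  expect_equal(nf$total_rate, 5.1530, tolerance = 1e-12)
  of <- releaseFlux(3.6e6, 986.3, pi * 17.4e-3^2)
  expect_equal(of$total_rate_per_h, 986.3 * 36)
  expect_equal(of$total_rate / nf$total_rate, 986.3 / 515.3)
  expect_equal(round(of$total_rate / nf$total_rate, 1), 1.9)
  expect_equal(nf$flux * pi * 17.4e-3^2, nf$total_rate)
  expect_error(releaseFlux(0, 515.3, 1), "positive")
  expect_error(releaseFlux(1e5, 515.3, 0), "positive")
})

test_that("transwell counts are cumulative, bounded and source-monotone", {
  cfg_nf <- transwellConfig("NF", duration = 2 * 3600, n_steps = 120L,
                            nr = 24L, nz = 30L)
  cfg_of <- transwellConfig("OF", duration = 2 * 3600, n_steps = 120L,
                            nr = 24L, nz = 30L)
  rn <- runTranswell(cfg_nf)
  ro <- runTranswell(cfg_of)
  # non-decreasing cumulative flux, starting from zero concentration
  expect_true(all(diff(rn$membrane$count) >= -1e-9 * max(rn$membrane$count)))
  # bounded by the total released
  expect_lte(max(rn$membrane$count),
             rn$release$total_rate * 2 * 3600 * (1 + 1e-9))
  # OF dominates NF pointwise in both counting modes
  expect_true(all(ro$membrane$count >= rn$membrane$count))
  cn <- membraneCount(rn, "region_content")
  co <- membraneCount(ro, "region_content")
  expect_true(all(co$count >= cn$count))
  # bottom-heavy gradient while filling (difference formed at the
  # resolved deviation level)
  expect_true(all(rn$history$monitors$bottom_minus_top > 0))
})

test_that("transwell membrane count ratio equals the source ratio exactly", {
  mk <- function(cond) runTranswell(
    transwellConfig(cond, duration = 3600, n_steps = 60L, nr = 20L, nz = 24L))
  rn <- mk("NF"); ro <- mk("OF")
  ratio <- ro$membrane$count / rn$membrane$count
  expect_equal(ratio, rep(986.3 / 515.3, length(ratio)), tolerance = 1e-9)
})

test_that("fast-diffusion limit matches the well-mixed closed-form count", {
  # with huge Gamma the chamber is quasi-uniform, so the content of the
  # membrane-adjacent region grows as (V_region / V_total) S t
  cfg <- transwellConfig("NF", gamma = 10, duration = 3600, n_steps = 120L,
                         nr = 24L, nz = 30L, counting = "region_content")
  r <- runTranswell(cfg)
  geo <- r$grid
  memb <- r$mask$membrane
  Vregion <- sum(geo$V[memb$i, memb$j])
  Vtotal <- sum(geo$V[!r$mask$solid])
  S <- r$release$total_rate
  expected <- (Vregion / Vtotal) * S * r$membrane$time_s
  late <- r$membrane$time_s > 600   # after the uniformization transient
  expect_equal(r$membrane$count[late], expected[late], tolerance = 0.01)
})

test_that("transwell conservation: domain content equals released total", {
  cfg <- transwellConfig("NF", duration = 3600, n_steps = 100L,
                         nr = 20L, nz = 24L)
  r <- runTranswell(cfg)
  S <- r$release$total_rate
  expect_equal(r$history$mass[, 1], S * r$history$times,
               tolerance = 1e-10)
})

test_that("TME runs obey one-way coupling and linear source scaling", {
  lay <- tinyTmeLayout()
  base <- tmeConfig(lay, nx = 64L, duration = 240)
  r0 <- runTme(tmeConfig(lay, nx = 64L, duration = 240, release_rate = 0),
               streamline_seeds = 0L)
  expect_equal(max(abs(r0$concentration)), 0)
  r1 <- runTme(base, streamline_seeds = 0L)
  r3 <- runTme(tmeConfig(lay, nx = 64L, duration = 240, release_rate = 7.5),
               streamline_seeds = 0L)
  # flow is identical (one-way coupling)
  expect_identical(r0$flow$uf, r1$flow$uf)
  expect_equal(r3$summary$mean_concentration / r1$summary$mean_concentration,
               3.0, tolerance = 1e-12)
  expect_equal(r3$concentration, 3 * r1$concentration, tolerance = 1e-12)
  # discrete release/outflow/accumulation balance closes
  expect_lt(r1$summary$balance_residual, 1e-10)
})

test_that("late-stage TME shows higher pressure and concentration", {
  early <- runTme(tmeConfig(tinyTmeLayout("early"), nx = 64L, duration = 240),
                  streamline_seeds = 4L)
  late <- runTme(tmeConfig(tinyTmeLayout("late"), nx = 64L, duration = 240),
                 streamline_seeds = 4L)
  ss <- stageSummary(early, late)
  expect_gt(ss$max_pressure_ratio, 1)
  expect_gt(ss$pressure_drop_ratio, 1)
  # larger tumor + 3x release: concentration ratio at least the source ratio
  expect_gt(ss$concentration_ratio, 3.0)
  expect_identical(stageSummary(early, early)$concentration_ratio, 1)
  # streamlines avoid the tumor
  for (pl in late$streamlines) {
    g <- late$grid
    ii <- pmin(g$nx, pmax(1L, 1L + floor(pl[, 1] / g$dx)))
    jj <- pmin(g$ny, pmax(1L, 1L + floor(pl[, 2] / g$dy)))
    expect_false(any(late$mask$solid[cbind(ii, jj)]))
  }
})
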