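# Closed-form speed curves and their analytic properties.

test_that("realised speed matches direct arithmetic for all three models", {
  p <- ref_params()
  # hump-shaped model, plain-arithmetic oracle
  f_direct <- function(M, v0, k, cc, d) {
    (1 / k) * M^cc / (M^(cc + d) + 1 / (v0 * k))
  }
  expect_equal(
    realised_speed(1, "flying", p),
    f_direct(1, 30.54, 0.033, 0.27, 0.24),
    tolerance = 1e-12
  )
  expect_equal(realised_speed(1, "flying", p), 15.21, tolerance = 1e-3)
  expect_equal(
    realised_speed(74000, "swimming", p),
    f_direct(74000, 0.39, 0.033, 0.27, 0.24),
    tolerance = 1e-12
  )
  expect_equal(realised_speed(74000, "swimming", p), 1.64, tolerance = 5e-3)

  # metabolic model at M = 1 kg returns v0 of the mode
  pm <- speed_params(v0 = c(flying = 30.54, running = 0.28), c = 0.27, sigma = 0.3)
  expect_equal(realised_speed(1, "flying", pm), 30.54)
  expect_equal(realised_speed(1, "running", pm), 0.28)

  # saturating model approaches 1/k0 from below at huge mass
  ps <- speed_params(v0 = c(running = 0.28), c = 0.27, sigma = 0.3, k0 = 0.05)
  v_huge <- realised_speed(1e12, "running", ps)
  expect_lt(v_huge, 1 / 0.05)
  expect_gt(v_huge, 0.95 / 0.05)
  expect_gt(realised_speed(1e13, "running", ps), v_huge)
})

test_that("evaluation is finite and accurate across 20+ orders of magnitude of mass", {
  p <- ref_params()
  m <- 10^seq(-12, 12, by = 1)
  v <- realised_speed(m, "running", p)
  expect_true(all(is.finite(v) & v > 0))
  # log-space evaluation agrees with naive arithmetic where the latter works
  naive <- (1 / 0.033) * m^0.27 / (m^0.51 + 1 / (0.28 * 0.033))
  expect_equal(v, naive, tolerance = 1e-10)
})

test_that("both heat-dissipation models converge to the potential speed at small mass", {
  p <- ref_params()
  ps <- speed_params(v0 = p$v0, c = p$c, sigma = p$sigma, k0 = p$k_lambda)
  for (mode in speed_modes()) {
    m <- 1e-12 # M^c and M^(c+d) << 1/(v0 k) for every mode here
    pot <- potential_speed(m, mode, p)
    expect_equal(realised_speed(m, mode, p), pot, tolerance = 1e-3)
    expect_equal(realised_speed(m, mode, ps), pot, tolerance = 1e-3)
  }
})

test_that("model nesting: d = 0 collapses hump onto saturating, k -> 0 onto power law", {
  m <- 10^seq(-8, 6, length.out = 60)
  p0 <- speed_params(
    v0 = c(running = 0.28), c = 0.27, d = 0, k_lambda = 0.05, sigma = 0.3
  )
  ps <- speed_params(v0 = c(running = 0.28), c = 0.27, k0 = 0.05, sigma = 0.3)
  expect_equal(
    realised_speed(m, "running", p0),
    realised_speed(m, "running", ps),
    tolerance = 1e-12
  )
  # k0 -> 0: saturating model converges to v0 * M^c
  pk <- speed_params(v0 = c(running = 0.28), c = 0.27, k0 = 1e-12, sigma = 0.3)
  expect_equal(
    realised_speed(m, "running", pk),
    potential_speed(m, "running", pk),
    tolerance = 1e-5
  )
})

test_that("hump-shaped curve is unimodal around peak_mass; others are monotone", {
  p <- ref_params()
  for (mode in speed_modes()) {
    mstar <- peak_mass(p, mode)
    grid <- 10^seq(log10(mstar) - 6, log10(mstar) + 6, length.out = 400)
    v <- realised_speed(grid, mode, p)
    below <- grid < mstar
    expect_true(all(diff(v[below]) > 0))
    expect_true(all(diff(v[!below]) < 0))
  }
  pm <- speed_params(v0 = c(running = 0.28), c = 0.27, sigma = 0.3)
  ps <- speed_params(v0 = c(running = 0.28), c = 0.27, k0 = 0.05, sigma = 0.3)
  grid <- 10^seq(-10, 10, length.out = 200)
  expect_true(all(diff(realised_speed(grid, "running", pm)) > 0))
  expect_true(all(diff(realised_speed(grid, "running", ps)) > 0))
})

test_that("peak_mass matches a dense grid search, including reference values", {
  p <- ref_params()
  grid_argmax <- function(params, mode, lo = -6, hi = 6) {
    g <- 10^seq(lo, hi, length.out = 200001)
    g[which.max(realised_speed(g, mode, params))]
  }
  expect_equal(peak_mass(p, "flying"), grid_argmax(p, "flying"), tolerance = 1e-3)
  expect_equal(peak_mass(p, "flying"), 1.24, tolerance = 1e-2)
  expect_equal(peak_mass(p, "swimming"), grid_argmax(p, "swimming"), tolerance = 1e-3)
  expect_equal(peak_mass(p, "swimming"), 6.4e3, tolerance = 1e-2)
  # swimmers peak in the 1e3..1e4 kg range; flyers four orders lower
  expect_true(dplyr::between(peak_mass(p, "swimming"), 1e3, 1e4))
  expect_gt(peak_mass(p, "running") / peak_mass(p, "flying"), 1e3)

  # property: closed form equals grid argmax for random parameter sets
  withr::with_seed(99, {
    for (i in 1:100) {
      rp <- random_ahd_params()
      mode <- sample(speed_modes(), 1)
      mstar <- peak_mass(rp, mode)
      expect_equal(mstar, grid_argmax(rp, mode, log10(mstar) - 3, log10(mstar) + 3),
                   tolerance = 1e-3)
    }
  })
})

test_that("peak mass scales as x^(-1/(c+d)) when v0 is multiplied by x", {
  withr::with_seed(4, {
    for (i in 1:20) {
      rp <- random_ahd_params()
      x <- 10^runif(1, -2, 2)
      rp2 <- rp
      rp2$v0 <- rp$v0 * x
      expect_equal(
        peak_mass(rp2, "flying"),
        peak_mass(rp, "flying") * x^(-1 / (rp$c + rp$d)),
        tolerance = 1e-10
      )
    }
  })
})

test_that("exponent bounds add the efficiency exponent to the power interval", {
  expect_equal(unname(exponent_bounds(c(0.80, 0.97), -0.67)), c(0.13, 0.30))
  expect_equal(unname(exponent_bounds(c(0.5, 0.5), -0.5)), c(0, 0))
  expect_equal(unname(exponent_bounds(c(0.75, 1.00), -0.67)), c(0.08, 0.33))
  # unordered input is sorted
  expect_equal(unname(exponent_bounds(c(0.97, 0.80), -0.67)), c(0.13, 0.30))
  tb <- theory_bounds(c(0.80, 0.97), -0.67, d_range = c(0.01, 0.37))
  expect_equal(unname(tb$c_range), c(0.13, 0.30))
  expect_equal(tb$d_range, c(0.01, 0.37))
})

test_that("domain and configuration errors are signalled", {
  p <- ref_params()
  expect_error(realised_speed(-1, "flying", p), class = "allospeed_error_domain")
  expect_error(realised_speed(0, "flying", p), class = "allospeed_error_domain")
  expect_error(realised_speed(1, "crawling", p), class = "allospeed_error_validation")
  # missing parameter for the requested model structure
  pm <- speed_params(v0 = c(flying = 30), c = 0.27, sigma = 0.3)
  expect_error(
    realised_speed(1, "flying", pm, spec = speed_model("allometric_hd")),
    class = "allospeed_error_config"
  )
  expect_error(realised_speed(1, "running", pm), class = "allospeed_error_config")
  # d = 0 has no interior maximum
  p0 <- speed_params(v0 = c(flying = 30), c = 0.27, d = 0, k_lambda = 0.03, sigma = 0.3)
  expect_error(peak_mass(p0, "flying"), class = "allospeed_error_no_peak")
  expect_error(speed_params(v0 = c(flying = 30), c = 0.27, sigma = 0.3,
                            k0 = 0.1, k_lambda = 0.1),
               class = "allospeed_error_config")
})
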