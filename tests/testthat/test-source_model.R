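test_that("coefficient polynomial evaluates c1*r^c2 + c3*r + c4 with zero-exponent convention", {
  kq <- coefficient_quad(-2.30569, -1.98e-2, 2.847e-2, 2.27378)
  # at r = 1 the power term collapses to c1 regardless of exponent
  expect_equal(eval_coefficient(1, kq), -2.30569 + 2.847e-2 + 2.27378,
               tolerance = 1e-12)
  expect_identical(eval_coefficient(1, coefficient_quad(0, 0, 0, 1)), 1)
  expect_identical(eval_coefficient(2, coefficient_quad(1, 2, 0, 0)), 4)
  # c1 * r^0 == c1: zero exponent means a constant power term
  expect_identical(eval_coefficient(3, coefficient_quad(5, 0, 0, 0)), 5)
  expect_error(eval_coefficient(0, kq), class = "brachycheck_domain_error")
  expect_error(eval_coefficient(-1, kq), class = "brachycheck_domain_error")
})

test_that("coefficient polynomial is linear in (c1, c3, c4) at fixed r", {
  set.seed(42)
  for (rep in 1:25) {
    q <- stats::runif(4, -5, 5)
    r <- stats::runif(1, 0.1, 10)
    s <- stats::runif(1, 0.1, 3)
    scaled <- coefficient_quad(s * q[1], q[2], s * q[3], s * q[4])
    expect_equal(eval_coefficient(r, scaled),
                 s * eval_coefficient(r, coefficient_quad(q[1], q[2], q[3], q[4])),
                 tolerance = 1e-12)
  }
})

test_that("radial dose function matches the fitted form and is normalized at 1 cm", {
  spec <- builtin_spec()
  expect_equal(radial_dose(spec, 1), 1.001 / 1.00021, tolerance = 1e-12)
  expect_lt(abs(radial_dose(spec, 1) - 1), 0.002)  # within 0.2% of 1
  # degenerate parameters give the identity
  expect_identical(radial_dose(flat_spec(), 1), 1)
  # monotone falloff at large radius for the real source
  expect_lt(radial_dose(spec, 10), radial_dose(spec, 1))
  expect_error(radial_dose(spec, 0), class = "brachycheck_domain_error")
  # cross-check against the independent transcription at several radii
  for (r in c(0.5, 1, 2, 5, 10))
    expect_equal(radial_dose(spec, r),
                 oracle_g(r, gmp_radial[["h"]], gmp_radial[["i"]],
                          gmp_radial[["j"]], gmp_radial[["k"]]),
                 tolerance = 1e-14)
})

test_that("anisotropy function reproduces the frozen reference value and oracle", {
  spec <- builtin_spec()
  # regression constant computed by independent hand evaluation of the
  # fitted form with the published coefficient rows, before this build
  expect_equal(as.double(anisotropy(spec, 1, 90)), 0.9977248100153464,
               tolerance = 1e-12)
  for (case in list(c(2, 30), c(5, 150), c(0.5, 60), c(1, 90)))
    expect_equal(as.double(anisotropy(spec, case[1], case[2])),
                 oracle_F(case[1], case[2], gmp_quads), tolerance = 1e-12)
  expect_error(anisotropy(spec, -1, 90), class = "brachycheck_domain_error")
  expect_error(anisotropy(spec, 1, 181), class = "brachycheck_domain_error")
  expect_error(anisotropy(spec, 1, -0.1), class = "brachycheck_domain_error")
})

test_that("constant-k anisotropy is exactly 1 over many random draws", {
  spec <- flat_spec()
  set.seed(7)
  r <- stats::runif(1e5, 0.05, 20)
  th <- stats::runif(1e5, 0, 180)
  v <- anisotropy(spec, r, th)
  expect_true(all(as.double(v) == 1))
})

test_that("anisotropy is continuous in theta and mirror-symmetric for symmetric quads", {
  spec <- builtin_spec()
  delta <- 1e-6
  for (r in c(0.5, 1, 5)) {
    th <- seq(5, 175, by = 10)
    expect_true(all(abs(as.double(anisotropy(spec, r, th + delta)) -
                        as.double(anisotropy(spec, r, th))) < 1e-6))
  }
  # with primed quads equal to the unprimed ones, F(r, theta) = F(r, 180 - theta)
  sym <- source_spec("sym", 0.35, 1.118, 73.83,
                     radial = c(h = 1, i = 0, j = 0, k = 0),
                     anisotropy = list(
                       k = c(0, 0, 0, 0.5),
                       a = gmp_quads$a, b = gmp_quads$b, e = gmp_quads$e,
                       a_prime = gmp_quads$a, b_prime = gmp_quads$b,
                       e_prime = gmp_quads$e))
  th <- c(10, 45, 80, 90)
  expect_equal(as.double(anisotropy(sym, 2, th)),
               as.double(anisotropy(sym, 2, 180 - th)), tolerance = 1e-12)
})

test_that("polar angles at the axis are clamped and flagged", {
  spec <- builtin_spec()
  v0 <- anisotropy(spec, 1, 0)
  expect_true(attr(v0, "clamped"))
  expect_true(is.finite(as.double(v0)))
  expect_equal(as.double(v0), as.double(anisotropy(spec, 1, 0.05)), tolerance = 1e-12)
  v <- anisotropy(spec, 1, c(0, 90, 180))
  expect_identical(attr(v, "clamped"), c(TRUE, FALSE, TRUE))
})

test_that("source configuration loading validates fields and exposes the built-in registry", {
  expect_true("GammaMedPlus-Ir192" %in% list_source_models())
  spec <- load_source_spec("GammaMedPlus-Ir192")
  expect_s3_class(spec, "source_spec")
  expect_equal(spec$radial[["h"]], 1.001)
  expect_equal(spec$radial[["i"]], 7.69e-3)
  expect_equal(spec$radial[["j"]], 2.1e-4)
  expect_equal(spec$radial[["k"]], 2.63)
  expect_equal(unclass(spec$anisotropy$k), c(-2.30569, -1.98e-2, 2.847e-2, 2.27378),
               ignore_attr = TRUE)
  expect_equal(unclass(spec$anisotropy$b_prime), c(-14.54, -1.5588e-1, -4.47e-1, 39.889),
               ignore_attr = TRUE)

  expect_error(load_source_spec("no-such-source"), class = "brachycheck_config_error")

  # missing mandatory field
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "x", dose_rate_constant = 1.1,
                        half_life_days = 74,
                        radial = list(h = 1, i = 0, j = 0, k = 0),
                        anisotropy = list()), f)
  expect_error(load_source_spec(f), class = "brachycheck_config_error")
  expect_error(load_source_spec(f), "active_length_cm")

  # invalid half-life
  yaml::write_yaml(list(name = "x", active_length_cm = 0.35,
                        dose_rate_constant = 1.1, half_life_days = -1,
                        radial = list(h = 1, i = 0, j = 0, k = 0),
                        anisotropy = list(k = c(0, 0, 0, 1), a = rep(0, 4),
                                          b = rep(0, 4), e = rep(0, 4),
                                          a_prime = rep(0, 4), b_prime = rep(0, 4),
                                          e_prime = rep(0, 4))), f)
  expect_error(load_source_spec(f), class = "brachycheck_config_error")

  # a radial fit that is not normalized near r0 is rejected
  expect_error(
    source_spec("bad", 0.35, 1.118, 73.83,
                radial = c(h = 1.2, i = 0, j = 0, k = 0),
                anisotropy = list(k = c(0, 0, 0, 1), a = rep(0, 4),
                                  b = rep(0, 4), e = rep(0, 4),
                                  a_prime = rep(0, 4), b_prime = rep(0, 4),
                                  e_prime = rep(0, 4))),
    class = "brachycheck_config_error")
})
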