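# TIACs and absorbed doses: bi-exponential fits, trapezoid + decay tail,
# local-deposition dose arithmetic and dose ratios.

test_that("bi-exponential parameters are recovered from noiseless curves", {
  t <- seq(0, 300, by = 4)
  y <- 0.5 * exp(-0.01 * t) + 0.2 * exp(-0.3 * t)
  f <- fit_biexponential(ntac("liver", t, y, decay_corrected = FALSE))
  expect_equal(f$A1, 0.5, tolerance = 1e-6)
  expect_equal(f$lambda1, 0.01, tolerance = 1e-6)
  expect_equal(f$A2, 0.2, tolerance = 1e-6)
  expect_equal(f$lambda2, 0.3, tolerance = 1e-6)
  expect_false(f$non_monotone)
})

test_that("a mono-exponential is absorbed as the nested degenerate case", {
  t <- c(4, 24, 48, 72, 144)
  y <- 0.4 * exp(-0.02 * t)
  f <- fit_biexponential(ntac("kidneys", t, y, decay_corrected = FALSE))
  expect_gt(f$r_squared, 0.9999)
  ti <- tiac_analytic(f$A1, f$lambda1, f$A2, f$lambda2)
  expect_equal(ti, 0.4 / 0.02, tolerance = 1e-3)
})

test_that("an uptake-then-washout curve raises the non-monotone flag", {
  t <- c(4, 24, 48, 72, 144)
  y <- 0.8 * (exp(-0.01 * t) - exp(-0.15 * t))   # rises to ~20 h then falls
  f <- fit_biexponential(ntac("uterus", t, y))
  expect_true(f$non_monotone)
})

test_that("analytic TIAC of a bi-exponential is A1/l1 + A2/l2", {
  expect_equal(tiac_analytic(1, 0.1), 10)
  expect_equal(tiac_analytic(0.5, 0.05, 0.5, 0.5), 11.0)
  expect_equal(tiac_analytic(0.7, 0.02, 0, 1), 35)
  expect_error(tiac_analytic(1, 0), "divergent")
  expect_error(tiac_analytic(1, 0.1, 0.5, -0.2), "divergent")
})

test_that("trapezoid integration plus physical-decay tail is exact on a plateau", {
  x <- ntac("stomach", c(0, 5, 10), rep(0.1, 3), decay_corrected = FALSE)
  got <- tiac_trapezoid_tail(x, lu177())
  expect_equal(got, 1 + 0.1 * 159.53 / log(2), tolerance = 1e-10)
})

test_that("densely sampled bi-exponentials agree with the analytic integral", {
  t <- seq(0.1, 2000, by = 0.5)
  nuc <- lu177()
  for (p in list(c(0.5, 0.01, 0.2, 0.3), c(0.9, 0.005, 0.05, 0.08))) {
    y <- p[1] * exp(-p[2] * t) + p[3] * exp(-p[4] * t)
    got <- tiac_trapezoid_tail(ntac("o", t, y, decay_corrected = FALSE), nuc)
    want <- tiac_analytic(p[1], p[2], p[3], p[4])
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("decay-corrected curves are decayed before integration", {
  t <- c(4, 24, 48, 72, 144)
  nuc <- lu177()
  phys <- 0.3 * exp(-0.002 * t) * exp(-nuc$lambda_phys * t)
  corrected <- 0.3 * exp(-0.002 * t)
  a <- tiac_trapezoid_tail(ntac("o", t, phys, decay_corrected = FALSE), nuc)
  b <- tiac_trapezoid_tail(ntac("o", t, corrected, decay_corrected = TRUE), nuc)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(tiac_trapezoid_tail(ntac("o", t, rep(0, 5)), nuc), 0)
})

test_that("the t0 policy controls the prepended starting value", {
  t <- c(10, 20)
  y <- c(0.4, 0.3)  # back-extrapolates to 0.5 at t = 0
  mk <- function(pol) tiac_trapezoid_tail(ntac("blood", t, y,
                                               decay_corrected = FALSE),
                                          lu177(), t0 = pol)
  lam <- lu177()$lambda_phys
  expect_equal(mk("extrapolate"), 0.45 * 10 + 0.35 * 10 + 0.3 / lam)
  expect_equal(mk("zero"), 0.2 * 10 + 0.35 * 10 + 0.3 / lam)
  expect_equal(mk("first"), 0.4 * 10 + 0.35 * 10 + 0.3 / lam)
})

test_that("local-deposition dose follows the unit conversion exactly", {
  d <- absorbed_dose(1, mass_g = 1, organ = "sphere")
  expect_equal(d$absorbed_dose_mGy_MBq, 85.30, tolerance = 1e-3)
  d2 <- absorbed_dose(1, mass_g = 2)
  expect_equal(d2$absorbed_dose_mGy_MBq, d$absorbed_dose_mGy_MBq / 2)
  # linear in TIAC and in the electron energy
  expect_equal(absorbed_dose(3, 1)$absorbed_dose_mGy_MBq,
               3 * d$absorbed_dose_mGy_MBq)
  nuc2 <- nuclide_data(delta_electron_keV = 2 * 147.9)
  expect_equal(absorbed_dose(1, 1, nuc2)$absorbed_dose_mGy_MBq,
               2 * d$absorbed_dose_mGy_MBq)
})

test_that("S-matrix doses combine source TIACs linearly", {
  S <- matrix(c(2, 0.1, 0.3, 1.5), 2, 2,
              dimnames = list(c("liver", "kidneys"), c("liver", "kidneys")))
  ti <- c(liver = 10, kidneys = 3)
  d <- absorbed_dose(ti, model = "s_matrix", s_matrix = S)
  expect_equal(d$absorbed_dose_mGy_MBq[d$organ == "liver"], 2 * 10 + 0.3 * 3)
  expect_equal(d$absorbed_dose_mGy_MBq[d$organ == "kidneys"], 0.1 * 10 + 1.5 * 3)
  expect_error(absorbed_dose(c(spleen = 1), model = "s_matrix", s_matrix = S),
               "lacks source")
})

test_that("dose ratios reproduce printed-table arithmetic", {
  tab3 <- data.frame(organ = c("tumor", "liver"),
                     absorbed_dose_mGy_MBq = c(2.53e3, 1.79e3))
  expect_equal(dose_ratio(tab3, "tumor", "liver", digits = 2), 1.41)
  tab4_3dota <- data.frame(organ = c("tumor", "liver"),
                           absorbed_dose_mGy_MBq = c(1.82e3, 2.23e3))
  expect_equal(dose_ratio(tab4_3dota, "tumor", "liver", digits = 1), 0.8)
  same <- data.frame(organ = c("a", "b"), absorbed_dose_mGy_MBq = c(5, 5))
  expect_equal(dose_ratio(same, "a", "b"), 1.0)
  expect_error(dose_ratio(tab3, "tumor", "spleen"), "not present")
})

test_that("TIAC uncertainty brackets the mean curve", {
  t <- c(4, 24, 48, 72, 144)
  mean_v <- 0.3 * exp(-0.01 * t)
  sd_v <- 0.1 * mean_v
  u <- tiac_with_uncertainty(t, mean_v, sd_v, organ = "liver")
  expect_lt(u$tiac_lo, u$tiac)
  expect_gt(u$tiac_hi, u$tiac)
  expect_equal(u$uncertainty, (u$tiac_hi - u$tiac_lo) / 2)
})
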