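# Covariate laws and the simultaneous fit across conjugates.

test_that("covariate laws produce the prescribed per-conjugate rates", {
  tr <- default_truth()
  cov <- tr$cov
  shared <- tr$shared
  p0 <- conjugate_profile("d0", dar = 0, immunoreactive_fraction = 0.8)
  expect_equal(rates_for_conjugate(cov, shared, p0)$k_up[["liver"]], 0)

  p1 <- conjugate_profile("d1", 1, 0.8)
  p3 <- conjugate_profile("d3", 3, 0.8)
  r1 <- rates_for_conjugate(cov, shared, p1)$k_up[["liver"]]
  r3 <- rates_for_conjugate(cov, shared, p3)$k_up[["liver"]]
  expect_equal(r3 / r1, 3)   # proportionality in DAR is exact

  cov2 <- covariate_model(0.005, tumor = c(0, 0.004), uterus = c(0, 0.001),
                          spleen = c(0, 0.0007), bone = c(0, 0.0015))
  hi <- rates_for_conjugate(cov2, shared, conjugate_profile("a", 1, 1))
  lo <- rates_for_conjugate(cov2, shared, conjugate_profile("b", 1, 0))
  expect_equal(hi$k_up[["spleen"]], 0)
  expect_equal(lo$k_up[["spleen"]], 0.0007)
  expect_equal(hi$k_up[["tumor"]], 0.004)
  expect_equal(lo$k_up[["tumor"]], 0)

  pna <- conjugate_profile("na", 2.5)
  expect_error(rates_for_conjugate(cov, shared, pna), "immunoreactive fraction")
})

test_that("the global fit recovers all coefficients from noiseless data", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  set.seed(1)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  start <- perturb_truth(default_truth())
  gf <- fit_global(dat, d$profiles, start$cov, start$shared)
  expect_true(gf$converged)
  truth_vec <- truth_param_vector(tr)
  expect_lt(max(abs(gf$estimates$estimate - truth_vec) / truth_vec), 1e-3)
  # the optimum can be no worse than the generator truth
  expect_lte(gf$rss, 1e-10)
})

test_that("forcing full immunoreactivity degrades the fit to low-IR data", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  profiles_ir1 <- lapply(d$profiles, function(p) {
    p$immunoreactive_fraction <- 1
    p
  })
  rss_at <- function(profiles) {
    sum(unlist(lapply(names(profiles), function(lb) {
      m <- rates_for_conjugate(tr$cov, tr$shared, profiles[[lb]])
      sub <- dat[dat$conjugate == lb, ]
      conc <- predict_concentrations(m, pk_solve(m, sort(unique(sub$time_h))))
      idx <- match(paste(sub$organ, sub$time_h), paste(conc$organ, conc$time_h))
      (sub$pct_ia_per_g - conc$pct_ia_per_g[idx])^2
    })))
  }
  expect_lt(rss_at(d$profiles), 1e-12)
  expect_gt(rss_at(profiles_ir1), 1)
  # and with IR forced to 1 everywhere, tumor uptake rates no longer differ
  kups <- vapply(profiles_ir1, function(p)
    rates_for_conjugate(tr$cov, tr$shared, p)$k_up[["tumor"]], numeric(1))
  expect_equal(unname(diff(range(kups))), 0)
})

test_that("tumor/liver ratio falls monotonically with DAR at fixed IR", {
  tr <- default_truth()
  profiles <- lapply(seq(1, 11, by = 2), function(d)
    conjugate_profile(paste0("d", d), d, 0.85))
  names(profiles) <- vapply(profiles, `[[`, character(1), "label")
  ratios <- predict_24h_panel(tr$cov, tr$shared, profiles)$ratios
  expect_true(all(diff(ratios$tumor_liver_ratio) < 0))
})

test_that("predicted panel under calibrated truth anti-correlates with DAR", {
  tr <- default_truth()
  d <- default_study_design()
  panel <- predict_24h_panel(tr$cov, tr$shared, d$profiles)
  sp <- spearman_ratio_vs_dar(panel$ratios$tumor_liver_ratio, panel$ratios$dar)
  expect_lte(sp$rho, -0.9)
  # the qualitative 24-h pattern: liver rises with DAR, tumor falls beyond DAR 3
  liver <- panel$panel[panel$panel$organ == "liver", ]
  liver <- liver[order(liver$dar), ]
  expect_true(all(diff(liver$pct_ia_per_g) > 0))
  tumor <- panel$panel[panel$panel$organ == "tumor", ]
  tumor <- tumor[order(tumor$dar), ]
  expect_true(all(diff(tumor$pct_ia_per_g[tumor$dar >= 3]) < 0))
})

test_that("a single distinct IR triggers the rank check and intercept fixing", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  same_ir <- lapply(d$profiles, function(p) {
    p$immunoreactive_fraction <- 0.85
    p
  })
  dat <- generate_biodistribution(
    structure(list(profiles = same_ir, time_points = d$time_points,
                   n_mice = 1, cv = d$cv), class = "study_design"),
    tr, mode = "model", cv_scale = 0)
  start <- default_truth()
  gf <- fit_global(dat, same_ir, start$cov, start$shared)
  expect_match(gf$rank_note, "intercepts fixed")
  expect_false("tumor.a" %in% gf$estimates$name)
})

test_that("missing IR without imputation is a configuration error", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  profs <- d$profiles
  profs$DAR2.5$immunoreactive_fraction <- NA_real_
  expect_error(fit_global(dat, profs, tr$cov, tr$shared), "impute")
})
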