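# Weighted Levenberg-Marquardt fitting of one conjugate's time course.

test_that("noiseless single-conjugate data are recovered to high precision", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  truth_model <- rates_for_conjugate(tr$cov, tr$shared, d$profiles$DAR3)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  dat <- dat[dat$conjugate == "DAR3", ]

  start <- truth_model
  start$k_up <- start$k_up * 1.5
  start$k_ret <- start$k_ret * 0.7
  start$k_ex <- start$k_ex * 1.3
  start$f_b <- pmin(start$f_b * 1.2, 0.9)
  fit <- fit_single(start, dat)
  expect_true(fit$converged)
  truth_vec <- c(truth_model$k_up, truth_model$k_ret, truth_model$k_ex,
                 truth_model$f_b)
  expect_lt(max(abs(fit$estimates$estimate - truth_vec) / truth_vec), 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("asymptotic 95% intervals cover the truth in most noisy replicates", {
  # scaled-down coverage study: two organs, three free rates, 5% CV, n = 3
  organs <- c("tumor", "liver")
  masses <- c(tumor = 0.21, liver = 1.13)
  truth <- pk_model(organs, k_up = c(tumor = 0.004, liver = 0.0065),
                    k_ret = c(tumor = 0.01, liver = 0.002), k_ex = 0.05,
                    f_b = c(tumor = 0.05, liver = 0.3),
                    organ_masses = masses, blood_mass = 1.42)
  times <- c(4, 24, 48, 72, 144)
  conc <- predict_concentrations(truth, pk_solve(truth, times))
  fix <- list(k_ret.tumor = 0.01, k_ret.liver = 0.002,
              f_b.tumor = 0.05, f_b.liver = 0.3)
  free_names <- c("k_up.tumor", "k_up.liver", "k_ex")
  truth_free <- c(0.004, 0.0065, 0.05)

  set.seed(2024)
  n_rep <- 100
  covered <- matrix(FALSE, n_rep, length(free_names))
  for (r in seq_len(n_rep)) {
    obs <- do.call(rbind, lapply(1:3, function(i) {
      d <- conc
      d$pct_ia_per_g <- pmax(d$pct_ia_per_g * (1 + stats::rnorm(nrow(d), 0, 0.05)), 0)
      d$animal_id <- i
      d
    }))
    start <- truth
    start$k_up <- start$k_up * 1.3
    start$k_ex <- start$k_ex * 0.8
    fit <- fit_single(start, obs, weights = "uniform", fix = fix)
    est <- fit$estimates
    covered[r, ] <- truth_free >= est$lower95[match(free_names, est$name)] &
      truth_free <= est$upper95[match(free_names, est$name)]
  }
  # pooled over parameters and replicates: nominal 95% intervals should
  # cover the truth in at least 90% of cases
  expect_gte(mean(covered), 0.9)
})

test_that("independent fits of the two full arms recover the liver uptake ratio", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  kups <- vapply(c("DAR1", "DAR3"), function(lb) {
    start <- rates_for_conjugate(tr$cov, tr$shared, d$profiles[[lb]])
    start$k_up <- start$k_up * 1.4
    fit_single(start, dat[dat$conjugate == lb, ])$model$k_up[["liver"]]
  }, numeric(1))
  # generator truth makes liver uptake proportional to DAR, ratio 3
  expect_equal(unname(kups["DAR3"] / kups["DAR1"]), 3, tolerance = 1e-3)
})

test_that("fit results are invariant to the ordering of the organ set", {
  tr <- default_truth()
  d <- default_study_design(n_mice = 1)
  dat <- generate_biodistribution(d, tr, mode = "model", cv_scale = 0)
  dat <- dat[dat$conjugate == "DAR1", ]
  base <- rates_for_conjugate(tr$cov, tr$shared, d$profiles$DAR1)
  start <- base
  start$k_up <- start$k_up * 1.3
  perm <- rev(base$organs)
  start_perm <- pk_model(perm, k_up = start$k_up[perm], k_ret = start$k_ret[perm],
                         k_ex = start$k_ex, f_b = start$f_b[perm],
                         organ_masses = start$organ_masses[perm],
                         blood_mass = start$blood_mass)
  f1 <- fit_single(start, dat)$model
  f2 <- fit_single(start_perm, dat)$model
  expect_equal(f1$k_up[sort(names(f1$k_up))], f2$k_up[sort(names(f2$k_up))],
               tolerance = 1e-6)
})

test_that("under-identified configurations are refused", {
  m <- random_pk_model(7)
  one_pt <- data.frame(conjugate = "x", time_h = 24,
                       organ = c("blood", m$organs), animal_id = 1,
                       pct_ia_per_g = 1)
  expect_error(fit_single(m, one_pt), "under-identified")
  fix_all_ret <- stats::setNames(as.list(rep(0, 8)), paste0("k_ret.", m$organs))
  expect_error(
    fit_single(m, one_pt[1:5, ], fix = fix_all_ret), "under-identified")
})

test_that("auto weights use within-group spread and fall back to uniform", {
  d <- data.frame(organ = rep(c("a", "b"), each = 4),
                  time_h = 24,
                  animal_id = rep(1:4, 2),
                  pct_ia_per_g = c(10, 11, 9, 10, 1, 1.2, 0.8, 1))
  w <- biodist_weights(d)
  expect_equal(mean(w), 1)
  expect_gt(mean(w[d$organ == "b"]), mean(w[d$organ == "a"]))
  # single animal per group: no SDs, uniform
  expect_equal(biodist_weights(d[c(1, 5), ]), c(1, 1))
})
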