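test_that("initial guesses land within a factor of 3 on clean curves", {
  cv <- model_curve("bm", list(K = 1, D = 0.5), R = 1)
  g <- initial_guess(cv, "bm")
  expect_false(attr(g, "degenerate"))
  expect_lt(abs(log(g[["K"]] / 1)), log(3))
  expect_lt(abs(log(g[["D"]] / 0.5)), log(3))
  # guesses respect bounds for every model
  for (mk in c("adm", "bm", "rbm")) {
    gg <- initial_guess(model_curve("bm", list(K = 2, D = 0.1), R = 2), mk)
    expect_true(all(gg >= 0))
    if ("alpha" %in% names(gg)) expect_lte(gg[["alpha"]], 1)
    if ("M" %in% names(gg)) expect_lte(gg[["M"]], 1)
  }
})

test_that("a flat curve is flagged degenerate", {
  tg <- log_grid(30)
  flat <- frap_curve(tg, rep(1, 30), bleach_radius = 1)
  g <- initial_guess(flat, "bm")
  expect_true(attr(g, "degenerate"))
})

test_that("noiseless round trips recover the generative parameters", {
  cases <- list(
    list(model = "adm", params = list(K = 1, D_alpha = 1, alpha = 0.7), R = 1),
    list(model = "adm", params = list(K = 2.5, D_alpha = 0.05, alpha = 0.55), R = 2),
    list(model = "bm", params = list(K = 1.2, D = 0.22), R = 0.5),
    list(model = "rbm", params = list(K = 0.8, D = 0.9, M = 0.85), R = 1.5)
  )
  for (cs in cases) {
    cv <- model_curve(cs$model, cs$params, cs$R, times = log_grid(80, -2, 3))
    f <- fit_recovery(cv, cs$model)
    expect_true(f$converged)
    for (nm in names(cs$params)) {
      expect_equal(fit_param(f, nm), cs$params[[nm]], tolerance = 1e-3,
                   label = sprintf("%s/%s", cs$model, nm))
    }
    expect_lt(f$chi2, 1e-8)
  }
})

test_that("derived Brownian D accompanies anomalous fits", {
  p <- list(K = 1, D_alpha = dispersion_from_alpha(0.5, 0.7), alpha = 0.7)
  cv <- model_curve("adm", p, R = 1, times = log_grid(80, -2, 3))
  f <- fit_recovery(cv, "adm")
  expect_equal(fit_param(f, "D"), 0.5, tolerance = 1e-3)
})

test_that("chi-square matches its definition and is order-invariant", {
  cv <- model_curve("bm", list(K = 1, D = 0.5), R = 1)
  perfect <- chi_square(cv, "bm", list(K = 1, D = 0.5), noise_sd = 0.02)
  expect_equal(perfect$chi2, 0, tolerance = 1e-12)
  off <- chi_square(cv, "bm", list(K = 1, D = 1), noise_sd = 0.02)
  expect_gt(off$chi2, 0)
  expect_equal(off$chi2_reduced, off$chi2 / (nrow(cv) - 2))
  # reordering points leaves the sum unchanged
  idx <- rev(seq_len(nrow(cv)))
  cv2 <- frap_curve(cv$time, cv$intensity, bleach_radius = 1)
  expect_equal(
    chi_square(cv2, "bm", list(K = 1, D = 1), 0.02)$chi2,
    sum(((as.numeric(bm_recovery(cv$time[idx], 1, 1, 1,
                                 series_settings(19, Inf))) -
            cv$intensity[idx]) / 0.02)^2)
  )
  expect_error(chi_square(cv, "bm", list(K = 1, D = 1), 0), "noise_sd")
})

test_that("reduced chi-square is ~1 when the noise level is honest", {
  cv <- model_curve("bm", list(K = 1, D = 0.5), R = 1,
                    times = experimental_time_grid(), noise_sd = 0.02,
                    seed = 31)
  f <- fit_recovery(cv, "bm", fit_options(noise_sd = 0.02))
  expect_equal(f$chi2_reduced, 1, tolerance = 3 / sqrt(f$df))
})

test_that("fits are invariant under time-unit rescaling", {
  tg <- log_grid(60, -2, 2)
  cv <- model_curve("bm", list(K = 1, D = 0.5), R = 1, times = tg,
                    noise_sd = 0.01, seed = 5)
  f1 <- fit_recovery(cv, "bm", fit_options(noise_sd = 0.01))
  s <- 10
  cv2 <- frap_curve(cv$time / s, cv$intensity, bleach_radius = 1)
  f2 <- fit_recovery(cv2, "bm", fit_options(noise_sd = 0.01))
  expect_equal(fit_param(f2, "D"), s * fit_param(f1, "D"), tolerance = 1e-4)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-6)
})

test_that("non-convergence is reported, not raised", {
  # two points cannot constrain three parameters meaningfully, but the
  # API contract is a result object either way
  cv <- frap_curve(log_grid(12), rep(c(0.7, 0.8), 6)[1:12], bleach_radius = 1)
  expect_error(f <- fit_recovery(cv, "rbm"), NA)
  expect_s3_class(f, "frap_fit")
})

test_that("model comparison ranks the generative model first on clean data", {
  cv <- model_curve("rbm", list(K = 1.2, D = 0.3, M = 0.8), R = 1,
                    times = log_grid(80, -2, 3))
  cmp <- compare_models(cv, fit_options(noise_sd = 0.01))
  expect_equal(cmp$model[1], "rbm")
  expect_lt(cmp$chi2[1], 1e-6)
  # free Brownian cannot produce the immobile plateau
  expect_gt(cmp$chi2[cmp$model == "bm"], cmp$chi2[cmp$model == "rbm"])
})

test_that("tidiers expose estimates and fit summaries", {
  cv <- model_curve("bm", list(K = 1, D = 0.5), R = 1)
  f <- fit_recovery(cv, "bm")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std_error", "at_bound"))
  gl <- glance(f)
  expect_equal(gl$model, "bm")
  expect_true(all(c("chi2", "chi2_reduced", "converged") %in% names(gl)))
  expect_length(residuals(f), nrow(cv))
  expect_length(fitted(f), nrow(cv))
})
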