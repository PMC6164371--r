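test_that("bleach profile evaluates the Gaussian-beam law", {
  expect_equal(bleach_profile(0, K = 2, w = 1), exp(-2))
  expect_equal(bleach_profile(0, K = 2, w = 7), exp(-2))
  expect_equal(bleach_profile(seq(0, 5), K = 0, w = 1), rep(1, 6))
  expect_equal(bleach_profile(1, K = 1, w = 1), exp(-exp(-2)))
  # decreasing in K, increasing in r
  expect_lt(bleach_profile(0.5, 2, 1), bleach_profile(0.5, 1, 1))
  expect_lt(bleach_profile(0.5, 2, 1), bleach_profile(1.5, 2, 1))
  expect_error(bleach_profile(1, K = 1, w = 0), "w")
  expect_error(bleach_profile(1, K = -1, w = 1), "K")
})

test_that("anomalous recovery series behaves at its limits", {
  tg <- 10^seq(-2, 2, length.out = 30)
  expect_equal(as.numeric(adm_recovery(tg, 1, 1, 0.6, K = 0)), rep(1, 30))
  # D_alpha = 0: time drops out
  v0 <- as.numeric(adm_recovery(tg, 1, 0, 0.6, K = 1))
  expect_equal(v0, rep(v0[1], 30))
  # huge times: full recovery
  expect_equal(as.numeric(adm_recovery(1e12, 1, 1, 0.6, K = 1)), 1,
               tolerance = 1e-6)
  expect_error(adm_recovery(-1, 1, 1, 0.6, 1), "t")
  expect_error(adm_recovery(1, 0, 1, 0.6, 1), "R")
})

test_that("19-term truncation matches a 200-term evaluation", {
  s19 <- series_settings(19)
  s200 <- series_settings(200)
  worst <- 0
  for (K in c(0.5, 1, 2, 3)) {
    for (R in c(0.5, 1, 3)) {
      for (D in c(0.1, 1)) {
        for (a in c(0.6, 0.8, 1)) {
          tg <- 10^seq(-2, 3, length.out = 40)
          d19 <- as.numeric(adm_recovery(tg, R, D, a, K, s19))
          d200 <- as.numeric(adm_recovery(tg, R, D, a, K, s200))
          b19 <- as.numeric(bm_recovery(tg, R, D, K, s19))
          b200 <- as.numeric(bm_recovery(tg, R, D, K, s200))
          worst <- max(worst, abs(d19 - d200), abs(b19 - b200))
        }
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("Brownian series starts at the depth identity and recovers to 1", {
  for (K in c(0.3, 1, 2.5)) {
    # t = 0 value realises sum_{n>=0} (-K)^n / (n! (n+1)) = (1 - e^-K)/K
    expect_equal(as.numeric(bm_recovery(0, 1, 0.5, K)), (1 - exp(-K)) / K,
                 tolerance = 1e-9)
    expect_equal(as.numeric(bm_recovery(1e12, 1, 0.5, K)), 1,
                 tolerance = 1e-6)
  }
  expect_equal(as.numeric(bm_recovery(0, 1, 0.5, 1e-9)), 1, tolerance = 1e-6)
  # t and R enter only through D t / R^2
  expect_equal(as.numeric(bm_recovery(4, 2, 0.7, 1.2)),
               as.numeric(bm_recovery(1, 1, 0.7, 1.2)))
})

test_that("restricted Brownian model is the stated convex combination", {
  tg <- 10^seq(-2, 2, length.out = 20)
  K <- 1.2; D <- 0.4
  bm <- as.numeric(bm_recovery(tg, 1, D, K))
  depth <- (1 - exp(-K)) / K
  expect_equal(as.numeric(rbm_recovery(tg, 1, D, K, M = 1)), bm)
  expect_equal(as.numeric(rbm_recovery(tg, 1, D, K, M = 0)), rep(depth, 20))
  for (M in c(0.25, 0.6, 0.9)) {
    expect_equal(as.numeric(rbm_recovery(tg, 1, D, K, M)),
                 (1 - M) * depth + M * bm)
  }
  # affine in M at fixed t
  v1 <- as.numeric(rbm_recovery(5, 1, D, K, 0.2))
  v2 <- as.numeric(rbm_recovery(5, 1, D, K, 0.8))
  vm <- as.numeric(rbm_recovery(5, 1, D, K, 0.5))
  expect_equal(vm, (v1 + v2) / 2, tolerance = 1e-12)
  expect_error(rbm_recovery(1, 1, D, K, M = 1.2), "M")
})

test_that("all three models are non-decreasing and bounded in (0, 1]", {
  tg <- 10^seq(-3, 4, length.out = 200)
  sweep <- expand.grid(K = c(0.5, 1.5, 3), R = c(0.5, 2), D = c(0.05, 1))
  for (i in seq_len(nrow(sweep))) {
    K <- sweep$K[i]; R <- sweep$R[i]; D <- sweep$D[i]
    for (v in list(
      as.numeric(adm_recovery(tg, R, dispersion_from_alpha(D, 0.7), 0.7, K)),
      as.numeric(bm_recovery(tg, R, D, K)),
      as.numeric(rbm_recovery(tg, R, D, K, 0.8))
    )) {
      expect_true(all(diff(v) >= -1e-12))
      expect_true(all(v > 0 & v <= 1 + 1e-12))
    }
  }
})

test_that("adm at alpha = 1 has Brownian R^2/D half-time scaling", {
  K <- 1.2; D <- 0.5
  half_time <- function(R) {
    v0 <- as.numeric(adm_recovery(0, R, D, 1, K))
    target <- (v0 + 1) / 2
    uniroot(function(t) as.numeric(adm_recovery(t, R, D, 1, K)) - target,
            c(1e-8, 1e8), tol = 1e-10)$root
  }
  # doubling R quadruples the half-time
  expect_equal(half_time(2) / half_time(1), 4, tolerance = 1e-6)
})

test_that("dispersion conversion and its inverse follow the sine relation", {
  expect_equal(dispersion_from_alpha(1, 0.5), 2 / pi)
  expect_equal(dispersion_from_alpha(2, 0.6), 2 * sin(0.6 * pi) / (0.6 * pi))
  expect_equal(dispersion_from_alpha(5, 1), 0, tolerance = 1e-12)
  expect_equal(dispersion_from_alpha(1, 0.5, method = "gamma"),
               1 / gamma(0.5))
  # round trip away from the degenerate limit
  for (a in c(0.3, 0.6, 0.95)) {
    expect_equal(alpha_to_diffusion(dispersion_from_alpha(1.7, a), a), 1.7)
  }
  expect_error(alpha_to_diffusion(1, 1), "alpha")
})

test_that("propagator tail exponent interpolates Gaussian to exponential", {
  expect_equal(green_exponent(1), 1)
  expect_equal(green_exponent(1e-9), 0.5, tolerance = 1e-8)
  expect_equal(green_exponent(0.6), 1 / 1.4)
  expect_error(green_exponent(2), "alpha")
})

test_that("model registry dispatches on the shared keys", {
  tg <- c(0.5, 5)
  expect_equal(
    as.numeric(frap_model("adm", tg, 1, list(K = 1, D_alpha = 0.3, alpha = 0.7))),
    as.numeric(adm_recovery(tg, 1, 0.3, 0.7, 1))
  )
  expect_equal(
    as.numeric(frap_model("rbm", tg, 1, list(K = 1, D = 0.3, M = 0.8))),
    as.numeric(rbm_recovery(tg, 1, 0.3, 1, 0.8))
  )
  expect_equal(model_params("adm"), c("K", "D_alpha", "alpha"))
  expect_error(frap_model("nope", tg, 1, list()), "arg")
})
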