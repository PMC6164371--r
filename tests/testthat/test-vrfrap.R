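make_series <- function(radii, term, values, se = 0.01) {
  tibble::tibble(bleach_radius = radii, term = term, estimate = values,
                 std_error = se)
}

test_that("regression against 1/R recovers exact generative lines", {
  radii <- c(0.32, 0.37, 0.44, 0.74)
  # confinement-law truth Mp = 0.75, L = 0.09 -> slope 0.0567, intercept 0.75
  s <- make_series(radii, "M", 0.75 + 0.63 * 0.09 / radii)
  reg <- regress_vs_inverse_radius(s, "M")
  expect_equal(reg$slope, 0.63 * 0.09, tolerance = 1e-10)
  expect_equal(reg$intercept, 0.75, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  # constant parameter: zero slope, intercept equal to the constant
  s0 <- make_series(c(1, 1.5, 2, 3), "alpha", rep(0.77, 4))
  reg0 <- regress_vs_inverse_radius(s0, "alpha")
  expect_equal(reg0$slope, 0, tolerance = 1e-12)
  expect_equal(reg0$intercept, 0.77, tolerance = 1e-12)
})

test_that("regression respects the radius cutoff and input checks", {
  radii <- c(0.5, 1, 1.5, 2, 2.5, 3)
  s <- make_series(radii, "alpha", 0.7 - 0.1 / radii)
  reg <- regress_vs_inverse_radius(s, "alpha", r_min = 1)
  expect_equal(reg$n_points, 4)
  expect_true(all(reg$radii > 1))
  expect_error(regress_vs_inverse_radius(s[1:2, ], "alpha"), "at least 3")
  dup <- make_series(rep(2, 4), "alpha", c(0.7, 0.71, 0.69, 0.7))
  expect_error(regress_vs_inverse_radius(dup, "alpha"), "degenerate")
})

test_that("regression is invariant under permutation of entries", {
  radii <- c(1, 1.5, 2, 2.5, 3)
  s <- make_series(radii, "alpha", 0.7 - 0.15 / radii + c(1, -1, 2, 0, -2) * 1e-3)
  r1 <- regress_vs_inverse_radius(s, "alpha")
  r2 <- regress_vs_inverse_radius(s[sample(5), ], "alpha")
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$intercept, r2$intercept)
})

test_that("extrapolation returns the intercept with its uncertainty", {
  s <- make_series(c(1, 1.5, 2, 3), "alpha", rep(0.72, 4))
  ex <- extrapolate_parameter(regress_vs_inverse_radius(s, "alpha"))
  expect_equal(ex$estimate, 0.72, tolerance = 1e-12)
  expect_lte(ex$conf_low, ex$estimate)
  expect_gte(ex$conf_high, ex$estimate)
})

test_that("slope signs drive the motion classification", {
  radii <- c(1, 1.5, 2, 2.5, 3)
  neg <- regress_vs_inverse_radius(
    make_series(radii, "alpha", 0.7 - 0.2 / radii + rnorm(5, sd = 1e-4)),
    "alpha"
  )
  pos_m <- regress_vs_inverse_radius(
    make_series(radii, "M", 0.8 + 0.1 / radii + rnorm(5, sd = 1e-4)), "M"
  )
  flat_m <- regress_vs_inverse_radius(
    make_series(radii, "M", 1 + c(1, -1, 0, 1, -1) * 1e-5), "M"
  )
  expect_equal(as.character(classify_motion(neg, NULL)), "ctrw_like")
  expect_equal(as.character(classify_motion(NULL, pos_m)), "domain_confined")
  expect_equal(as.character(classify_motion(NULL, flat_m)), "brownian")
  # flat M away from 1 is evidence of nothing
  mid_m <- regress_vs_inverse_radius(
    make_series(radii, "M", 0.8 + c(1, -1, 0, 1, -1) * 1e-5), "M"
  )
  expect_equal(as.character(classify_motion(NULL, mid_m)), "inconclusive")
  ev <- attr(classify_motion(neg, pos_m), "evidence")
  expect_s3_class(ev, "tbl_df")
})

test_that("domain-size estimation inverts the confinement law", {
  radii <- c(0.32, 0.37, 0.44, 0.74)
  reg <- regress_vs_inverse_radius(
    make_series(radii, "M", 0.80 + 0.063 / radii), "M"
  )
  est <- schram_domain_size(reg)
  expect_equal(est$L, 0.1, tolerance = 1e-9)
  expect_equal(est$Mp, 0.80, tolerance = 1e-9)
  expect_equal(est$confined_fraction, 0.20, tolerance = 1e-9)
  expect_true(est$valid)  # L = 0.1 < smallest radius 0.32
  # zero slope: no confinement
  reg0 <- regress_vs_inverse_radius(
    make_series(radii, "M", rep(1, 4)), "M"
  )
  est0 <- schram_domain_size(reg0)
  expect_equal(est0$L, 0)
  expect_equal(est0$confined_fraction, 0)
  # negative slope: flagged invalid
  regn <- regress_vs_inverse_radius(
    make_series(radii, "M", 0.9 - 0.05 / radii), "M"
  )
  expect_false(schram_domain_size(regn)$valid)
  # wrong parameter refused
  rega <- regress_vs_inverse_radius(
    make_series(radii, "alpha", 0.7 + 0.05 / radii), "alpha"
  )
  expect_error(schram_domain_size(rega), "M")
})

test_that("alpha crossover radius solves the unity crossing", {
  radii <- c(0.32, 0.37, 0.44, 0.74)
  reg <- regress_vs_inverse_radius(
    make_series(radii, "alpha", 1.2 - 0.032 / radii), "alpha"
  )
  cx <- alpha_crossover_radius(reg)
  expect_true(cx$valid)
  expect_equal(cx$crossover_radius, 0.16, tolerance = 1e-9)
  # intercept exactly 1: crossover at infinite radius
  reg1 <- regress_vs_inverse_radius(
    make_series(radii, "alpha", 1 - 0.05 / radii), "alpha"
  )
  expect_equal(alpha_crossover_radius(reg1)$crossover_radius, Inf)
  # intercept < 1 with negative slope never reaches 1
  regn <- regress_vs_inverse_radius(
    make_series(radii, "alpha", 0.8 - 0.05 / radii), "alpha"
  )
  expect_false(alpha_crossover_radius(regn)$valid)
})

test_that("vr series fitting collates tidy per-curve estimates", {
  radii <- c(0.32, 0.44, 0.74)
  curves <- lapply(radii, function(R) {
    model_curve("rbm", list(K = 1.2, D = 0.22, M = 0.75 + 0.0567 / R), R,
                times = experimental_time_grid())
  })
  s <- fit_vr_series(curves, "rbm", fit_options(noise_sd = 0.01))
  expect_s3_class(s, "vr_series")
  expect_setequal(unique(s$term), c("K", "D", "M"))
  m <- s[s$term == "M", ]
  expect_equal(m$estimate, 0.75 + 0.0567 / radii, tolerance = 1e-3)
  reg <- regress_vs_inverse_radius(s, "M")
  est <- schram_domain_size(reg)
  expect_equal(est$L, 0.09, tolerance = 0.01)
  expect_equal(est$Mp, 0.75, tolerance = 0.01)
})
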