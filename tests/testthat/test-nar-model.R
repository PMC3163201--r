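# Steady-state NAR model: binding algebra, the square-root law, composed
# input functions, and the cooperativity scan.

test_that("inducer binding and conservation are exact", {
  expect_equal(x_active(10, 3, 3), 5)          # s = K_s: half bound
  expect_equal(x_active(4, 3, 1), 3)           # 4 * 3/4
  expect_equal(x_active(7, 1e12, 1), 7, tolerance = 1e-10)  # saturation
  expect_error(x_active(-1, 1, 1), ">= 0")

  expect_identical(x_free(4, 3), 1)
  expect_identical(x_free(4, 0), 4)
  expect_identical(x_free(4, 4), 0)
  expect_error(x_free(4, 5), "exceed")

  # conservation X_f + X* = X to machine precision across magnitudes
  for (X in c(1e-6, 1, 1e8)) for (s in c(0, 1e-3, 1, 1e6)) {
    Xs <- x_active(X, s, 1)
    expect_identical(x_free(X, Xs) + Xs, X)
  }
})

test_that("closed-form steady state follows the square-root law", {
  p <- nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 2)
  expect_equal(p$A, 1)
  expect_equal(x_steady_closed_form(0, p), p$A)
  expect_equal(x_steady_closed_form(3 * p$K_s, p), 2 * p$A)
  expect_equal(x_steady_closed_form(99 * p$K_s, p), 10 * p$A)
})

test_that("exact steady state solves the self-repression balance", {
  # quadratic oracle at s = 0, K_x = 1, beta_x = 100, alpha = 1:
  # 100/(1 + X) = X has root (-1 + sqrt(401))/2
  p <- nar_params(beta_x = 100, alpha = 1, K_x = 1, K_s = 1)
  expect_equal(x_steady_exact(0, p), (-1 + sqrt(401)) / 2, tolerance = 1e-9)

  # weak self-repression: X approaches the unrepressed balance beta_x/alpha
  pw <- nar_params(beta_x = 100, alpha = 2, K_x = 1e9, K_s = 1)
  expect_equal(x_steady_exact(0, pw), 50, tolerance = 1e-6)

  # strong-binding limit agreement with the closed form (< 0.5%)
  pl <- nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 1)  # K_x = 1e-6 A
  s <- c(0, 3, 99)
  rel <- x_steady_exact(s, pl) / x_steady_closed_form(s, pl) - 1
  expect_true(all(abs(rel) < 0.005))

  # the residual of the balance equation vanishes at the root
  s2 <- 10^seq(-4, 6, length.out = 21)
  X <- x_steady_exact(s2, p)
  Xf <- X * p$K_s / (p$K_s + s2)
  resid <- p$beta_x / (1 + Xf / p$K_x) - p$alpha * X
  expect_true(all(abs(resid) < 1e-8 * p$beta_x / p$alpha))

  # monotone nondecreasing in the signal
  expect_true(all(diff(X) > 0))
})

test_that("composed input functions reach the model dynamic ranges", {
  # with-NAR, n = 2, K_z/A = 100, closed-form X: R ~ 81 and the crossing
  # points match the quadratic oracle
  p <- nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 1,
                  beta_z = 1, K_z = 100, n = 2)
  dr <- dynamic_range_numeric(input_function_with_nar(p, "closed_form"))
  expect_equal(dr$R, 81, tolerance = 0.05)  # within 5%
  expect_equal(dr$s10, with_nar_crossing_oracle(0.1, 100, 1),
               tolerance = 1e-6)
  expect_equal(dr$s90, with_nar_crossing_oracle(0.9, 100, 1),
               tolerance = 1e-6)
  expect_equal(dr$s10, 1112.1, tolerance = 1e-3)
  expect_equal(dr$s90, 90001, tolerance = 1e-3)

  # exact solver in the same regime agrees
  dre <- dynamic_range_numeric(input_function_with_nar(p, "exact"))
  expect_equal(dre$R, dr$R, tolerance = 0.01)

  # no-NAR, n = 2, K_z/X0 = 1e-3: R ~ 9, crossings from the oracle
  p0 <- nar_params(K_s = 1, beta_z = 1, K_z = 1, n = 2, X0 = 1000)
  dr0 <- dynamic_range_numeric(input_function_no_nar(p0))
  expect_equal(dr0$R, 9, tolerance = 0.05)
  expect_equal(dr0$s10, no_nar_crossing_oracle(0.1, 1, 1000, 1),
               tolerance = 1e-6)
  expect_equal(dr0$s90, no_nar_crossing_oracle(0.9, 1, 1000, 1),
               tolerance = 1e-6)
  expect_equal(dr0$s10, 3.334e-4, tolerance = 1e-3)
  expect_equal(dr0$s90, 3.009e-3, tolerance = 1e-3)

  # hyperbolic promoter (n = 1) keeps R ~ 81 even without NAR
  p1 <- nar_params(K_s = 1, beta_z = 1, K_z = 1, n = 1, X0 = 1000)
  expect_equal(dynamic_range_numeric(input_function_no_nar(p1))$R, 81,
               tolerance = 0.05)

  # both curves vanish at zero signal and are monotone on a log grid
  s <- c(0, 10^seq(-6, 10, length.out = 40))
  fw <- input_function_with_nar(p, "closed_form")
  f0 <- input_function_no_nar(p0)
  expect_identical(fw(0), 0)
  expect_identical(f0(0), 0)
  expect_true(all(diff(fw(s)) >= 0))
  expect_true(all(diff(f0(s)) >= 0))
})

test_that("dynamic range is invariant to joint dimensional rescaling", {
  base <- dynamic_range_numeric(input_function_with_nar(
    nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 1,
               beta_z = 1, K_z = 100, n = 2), "exact"))
  # rescale the signal scale K_s
  sig <- dynamic_range_numeric(input_function_with_nar(
    nar_params(beta_x = 1e6, alpha = 1, K_x = 1e-6, K_s = 250,
               beta_z = 1, K_z = 100, n = 2), "exact"))
  expect_equal(sig$R, base$R, tolerance = 1e-6)
  expect_equal(sig$s10, 250 * base$s10, tolerance = 1e-6)
  # rescale all concentrations (K_x, K_z, A) by c: beta_x -> c * beta_x
  conc <- dynamic_range_numeric(input_function_with_nar(
    nar_params(beta_x = 1e6 * 50, alpha = 1, K_x = 50e-6, K_s = 1,
               beta_z = 1, K_z = 100 * 50, n = 2), "exact"))
  expect_equal(conc$R, base$R, tolerance = 1e-6)
})

test_that("the cooperativity scan dominates the no-NAR benchmark", {
  sc <- scan_max_dynamic_range(n_grid = c(1, 2, 4), resolution = 16)
  expect_identical(nrow(sc), 3L)
  expect_equal(sc$R_no_nar, 81^(1 / c(1, 2, 4)))
  expect_true(all(sc$R_max_nar >= sc$R_no_nar * (1 - 1e-3)))
  expect_true(all(diff(sc$R_max_nar) <= 1e-8))
  expect_true(all(diff(sc$R_no_nar) < 0))

  expect_error(scan_max_dynamic_range(n_grid = numeric(0)), "empty")
  expect_error(scan_max_dynamic_range(n_grid = c(0.5, 2)), "within")
})
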