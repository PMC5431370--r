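test_that("memductance is the flux-controlled conductance alpha + 3 beta phi^2", {
  p <- model_params(alpha = 1, beta = 2)
  expect_identical(memductance(0, p), 1.0)
  expect_identical(memductance(1, p), 7.0)
  # even symmetry and lower bound alpha for beta >= 0, random coefficients
  set.seed(42)
  for (i in 1:20) {
    p2 <- model_params(alpha = runif(1, -2, 2), beta = runif(1, 0, 3))
    phi <- runif(50, -5, 5)
    expect_equal(memductance(-phi, p2), memductance(phi, p2))
    expect_true(all(memductance(phi, p2) >= p2$alpha))
  }
})

test_that("rate functions match a literal transcription of the kinetics", {
  # independent oracle: the printed formulas evaluated by parsing their
  # algebraic text, never the package's own arithmetic
  eval_expr <- function(txt, env) eval(parse(text = txt), envir = env)
  set.seed(7)
  p <- model_params(k0 = 0.37, I_st = 0.11, k1 = 0.8, k2 = 1.3,
                    alpha = 0.6, beta = 1.9)
  env0 <- as.list(p)
  n <- 1000L
  u <- runif(n, -0.25, 1.5); v <- runif(n, -0.5, 2); phi <- runif(n, -2, 2)
  env <- c(env0, list(u = u, v = v, phi = phi))
  exp_base <- eval_expr("-k*u*(u-a)*(u-1.0) - u*v + I_st", env)
  exp_ind <- eval_expr("-k*u*(u-a)*(u-1.0) - u*v + k0*(alpha+3*beta*phi^2)*u",
                       env)
  exp_v <- eval_expr("(eps + v*mu1/(u+mu2)) * (-v - k*u*(u-a-1.0))", env)
  exp_p <- eval_expr("k1*u - k2*phi", env)
  tol <- 1e-12 * pmax(1, abs(exp_ind))
  expect_true(all(abs(rate_u(u, v, phi, p, "baseline") - exp_base) <= tol))
  expect_true(all(abs(rate_u(u, v, phi, p, "induction") - exp_ind) <= tol))
  expect_true(all(abs(rate_v(u, v, p) - exp_v) <=
                    1e-12 * pmax(1, abs(exp_v))))
  expect_true(all(abs(rate_phi(u, phi, p) - exp_p) <=
                    1e-12 * pmax(1, abs(exp_p))))
})

test_that("rest state (0,0,0) is an exact equilibrium with I_st = 0", {
  p <- model_params()  # defaults have I_st = 0
  expect_true(rate_u(0, 0, 0, p, "induction") == 0)
  expect_true(rate_u(0, 0, 0, p, "baseline") == 0)
  expect_true(rate_v(0, 0, p) == 0)
  expect_true(rate_phi(0, 0, p) == 0)
})

test_that("spot values of the rates are exact", {
  p <- model_params(k0 = 0.1)
  # at u = 1, v = 0 the cubic and -uv terms vanish: only k0*alpha*u remains
  expect_equal(rate_u(1, 0, 0, p, "induction"), 0.1)
  # (eps + 0) * (-0 - 8 * 1 * (1 - 0.15 - 1)) = 0.002 * 1.2
  expect_equal(rate_v(1, 0, p), 0.0024)
  # frozen u = 1: equilibrium flux k1 * u / k2
  expect_equal(rate_phi(1, 0.5, model_params(k1 = 0.5, k2 = 1)), 0)
})

test_that("induction mode with k0 = 0 degenerates to the baseline reaction", {
  set.seed(11)
  p <- model_params(k0 = 0, I_st = 0)
  u <- runif(200, -0.3, 1.4); v <- runif(200, -1, 2); phi <- runif(200, -3, 3)
  expect_equal(rate_u(u, v, phi, p, "induction"),
               rate_u(u, v, phi, p, "baseline"))
})

test_that("recovery rate raises a domain error on the u = -mu2 line", {
  p <- model_params()
  expect_error(rate_v(-p$mu2, 0.5, p), "u \\+ mu2")
  expect_error(rate_v(-p$mu2 + 1e-15, 0.5, p), "u \\+ mu2")
  # configurable guard width
  expect_silent(rate_v(-p$mu2 + 1e-6, 0.5, p, guard = 1e-9))
  expect_error(rate_v(-p$mu2 + 1e-6, 0.5, p, guard = 1e-3))
})

test_that("frozen-u flux relaxation matches the closed-form linear ODE", {
  # phi' = k1 u0 - k2 phi with u frozen: phi(t) = phi_inf (1 - e^{-k2 t})
  p <- model_params(k1 = 0.5, k2 = 1)
  u0 <- 1
  phi_inf <- p$k1 * u0 / p$k2
  h <- 1e-4
  tr <- integrate_cell(cell_state(u = u0, v = 0, phi = 0), p,
                       duration = 10, h = h, freeze = c("u", "v"),
                       stride = 100L)
  exact <- phi_inf * (1 - exp(-p$k2 * tr$t))
  expect_lt(max(abs(tr$phi - exact)), 1e-4)
  expect_equal(tr$u, rep(u0, nrow(tr)))  # frozen variables stay put

  # Euler error is O(h): halving h about halves the max error
  err_at <- function(h) {
    tr <- integrate_cell(cell_state(u = u0, v = 0, phi = 0), p,
                         duration = 10, h = h, freeze = c("u", "v"),
                         stride = max(1L, round(0.1 / h)))
    max(abs(tr$phi - phi_inf * (1 - exp(-p$k2 * tr$t))))
  }
  e1 <- err_at(2e-3); e2 <- err_at(1e-3)
  expect_equal(e1 / e2, 2, tolerance = 0.1)
})

test_that("single-cell integrator is deterministic and flags divergence", {
  p <- model_params(k0 = 0.1)
  s0 <- cell_state(0.7, 0.6, 0.1)
  tr1 <- integrate_cell(s0, p, duration = 30, h = 0.03)
  tr2 <- integrate_cell(s0, p, duration = 30, h = 0.03)
  expect_identical(tr1, tr2)
  expect_true(all(is.finite(as.matrix(tr1))))
  # rest state stays at rest
  tr0 <- integrate_cell(cell_state(0, 0, 0), p, duration = 5, h = 0.03)
  expect_true(all(as.matrix(tr0)[, c("u", "v", "phi")] == 0))
  # a state pushed into runaway growth aborts rather than returning NaN
  expect_error(
    integrate_cell(cell_state(0.5, 0, 0), model_params(k0 = 50, k2 = 0),
                   duration = 50, h = 0.03, blowup = 1e3),
    "diverged")
})

test_that("trajectory stride subsamples without changing the dynamics", {
  p <- model_params(k0 = 0.1)
  s0 <- cell_state(0.7, 0.6, 0.1)
  full <- integrate_cell(s0, p, duration = 3, h = 0.03)
  strided <- integrate_cell(s0, p, duration = 3, h = 0.03, stride = 10L)
  expect_equal(strided, full[full$t %in% strided$t, ],
               ignore_attr = TRUE)
})
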