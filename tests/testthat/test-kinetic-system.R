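test_that("default linear open system matches its printed parameterization", {
  sys <- linear_system()
  expect_equal(sys$A[2, 1], 200)
  expect_equal(sys$A[1, 2], 300)
  expect_equal(sys$b[1], 100)
  expect_equal(sys$x0, rep(1, 11))
  expect_equal(sys$sub, 1e3 * c(0.2, 0.1, 0.5, 0.3, 2, 1, 3, 0.4, 1, 0.4))
  expect_equal(sys$sup, 1e3 * c(0.3, 0.5, 2, 2, 0.3, 3, 0.5, 1, 0.2, 0.4))
  # mass conservation closure: columns 1..10 sum to zero, open efflux at 11
  expect_lt(max(abs(colSums(sys$A)[1:10])), 1e-9 * max(abs(sys$A)))
  expect_equal(sys$A[11, 11], -1000)
  # tridiagonal: everything off the three bands is zero
  off <- abs(row(sys$A) - col(sys$A)) > 1
  expect_true(all(sys$A[off] == 0))
})

test_that("degenerate-case variant has the stated diagonal and off-diagonals", {
  sys <- degenerate_linear_system()
  expect_equal(diag(sys$A), unname(1e3 * c(-1, rep(-2, 10))),
               ignore_attr = TRUE)
  expect_true(all(sys$sub == 1e3) && all(sys$sup == 1e3))
  expect_equal(sys$b[1], 500)
})

test_that("sampling grids match their constructions", {
  tg <- linear_time_grid()
  expect_equal(tg[1], 0.012)
  expect_equal(tg[length(tg)], 0.202)
  expect_length(tg, 20)
  expect_equal(unique(round(diff(tg), 12)), 0.010)

  ct <- cholesterol_time_grid()
  expect_equal(ct[1], 0)
  expect_length(ct, 21)
  expect_true(all(diff(ct) > 0))
  # second point is the 25th entry of the 1000-point logarithmic source grid
  expect_equal(ct[2], 10^(24 * 6 / 999) - 1)
})

test_that("parameter perturbation respects the beta bound and mass closure", {
  sys <- linear_system()
  set.seed(1)
  expect_identical(perturb_parameters(sys, 0)$A, sys$A)

  set.seed(2)
  p <- perturb_parameters(sys, 0.01)
  expect_true(all(abs(p$sub / sys$sub - 1) <= 0.01))
  expect_true(all(abs(p$sup / sys$sup - 1) <= 0.01))
  expect_lt(max(abs(colSums(p$A)[1:10])), 1e-9 * max(abs(p$A)))
  expect_equal(p$A[11, 11], -1000)

  # hard bound over many draws at beta = 0.3
  set.seed(3)
  worst <- max(replicate(1000, {
    q <- perturb_parameters(sys, 0.3)
    max(abs(c(q$sub / sys$sub, q$sup / sys$sup) - 1))
  }))
  expect_lte(worst, 0.3)
  expect_error(perturb_parameters(sys, -0.1), "non-negative")
})

test_that("induced variation halves the targeted rate and keeps closure", {
  sys <- linear_system()
  mod <- apply_induced_variation(sys, "A(7,6)", 0.5)
  expect_equal(mod$A[7, 6], 500)            # default 1e3 * 1 halved
  expect_lt(abs(sum(mod$A[, 6])), 1e-9 * max(abs(mod$A)))
  expect_identical(apply_induced_variation(sys, "A(7,6)", 0)$A, sys$A)
  expect_error(apply_induced_variation(sys, "A(5,2)", 0.5), "off-diagonal")
  expect_error(apply_induced_variation(sys, "notaparam", 0.5), "unknown")
  expect_error(apply_induced_variation(sys, "A(7,6)", 1), "\\[0, 1\\)")
})

test_that("linear trajectories agree with an independent stiff integrator", {
  sys <- linear_system()
  tg <- linear_time_grid()
  closed <- simulate_system(sys, tg)
  ode <- deSolve::ode(y = sys$x0, times = c(0, tg),
                      func = function(t, y, p) list(sys$A %*% y + sys$b),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  numeric_sol <- t(unclass(ode)[-1, -1])
  expect_lt(max(abs(closed - numeric_sol) / (abs(numeric_sol) + 1e-12)), 1e-6)
  # at t = 0 the state is x0
  expect_equal(unname(simulate_system(sys, 0)[, 1]), sys$x0)
})

test_that("long-horizon state approaches the algebraic steady state", {
  sys <- linear_system()
  xss <- steady_state(sys)
  expect_equal(unname(as.numeric(solve(sys$A) %*% -sys$b)), unname(xss))
  slowest <- 1 / min(abs(Re(eigen(sys$A, only.values = TRUE)$values)))
  far <- simulate_system(sys, 10 * slowest)[, 1]
  expect_lt(max(abs(far - xss) / abs(xss)), 1e-4)
})

test_that("generic kinetic systems integrate, perturb and knock down", {
  decay <- kinetic_system(
    rhs = function(x, p) c(p["in1"] - p["k1"] * x[1],
                           p["k1"] * x[1] - p["k2"] * x[2]),
    params = c(in1 = 1, k1 = 2, k2 = 1), x0 = c(0.1, 0.1))
  tr <- simulate_system(decay, c(0.5, 1, 5))
  # closed-form check for the first (autonomous linear) metabolite
  expect_equal(tr[1, "1"], 0.5 + (0.1 - 0.5) * exp(-2),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(unname(steady_state(decay, t_max = 50)), c(0.5, 1),
               tolerance = 1e-5)

  set.seed(7)
  pert <- perturb_parameters(decay, 0.1)
  expect_true(all(abs(pert$params / decay$params - 1) <= 0.1))
  kd <- apply_induced_variation(decay, "k2", 0.5)
  expect_equal(unname(kd$params["k2"]), 0.5)
  expect_error(apply_induced_variation(decay, "k9", 0.5), "unknown")
  expect_error(kinetic_system(function(x, p) x[1], params = c(a = 1),
                              x0 = c(1, 2)),
               "length")
})

test_that("model registry resolves built-ins and rejects unknown names", {
  expect_true(all(c("linear_open", "linear_degenerate") %in%
                    list_kinetic_models()))
  expect_s3_class(get_kinetic_model("linear_open"), "linear_system")
  expect_error(get_kinetic_model("no_such_model"), "available")
  toy <- kinetic_system(function(x, p) -p["k"] * x, c(k = 1), 1)
  register_kinetic_model("toy_decay", toy)
  expect_identical(get_kinetic_model("toy_decay"), toy)
})
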