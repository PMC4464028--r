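test_that("effective rate implements the feedback law", {
  expect_equal(effectiveRate(2.0, 1.0, 1.0), 1.0)
  expect_equal(effectiveRate(3.0, 0.5, 4.0), 1.0)
  # no feedback leaves the intrinsic rate untouched
  expect_equal(effectiveRate(1.7, 0, 12345), 1.7)
  expect_error(effectiveRate(-1, 0, 0), "non-negative")
  expect_error(effectiveRate(1, -0.1, 0), "non-negative")
})

test_that("effective rate is strictly decreasing in the TC count when h > 0", {
  tc <- seq(0, 1e5, length.out = 50)
  w <- effectiveRate(1.2, 3e-4, tc)
  expect_true(all(diff(w) < 0))
  expect_true(all(w <= 1.2))
})

test_that("CSC right-hand side matches hand-computed cases", {
  p0 <- cscParameters()
  expect_equal(cscRhs(rep(0, 5), p0), rep(0, 5))

  # only symmetric division active: dN_CSC/dt = P_sy * omega_CSC * N_CSC
  p <- cscParameters(P_sy = 1, omega_CSC = 2, omega_PC = 0, eta_1 = 0,
                     eta_2 = 0, eta_3 = 0, gamma_PC = 0, delta_1 = 0,
                     delta_2 = 0, delta_3 = 0, delta_4 = 0, h_CSC = 0,
                     h_PC = 0)
  expect_equal(cscRhs(c(1, 0, 0, 0, 0), p), c(2, 0, 0, 0, 0))

  # feedback halves omega_CSC at h_CSC * N_TC = 1
  p2 <- cscParameters(P_sy = 1, omega_CSC = 2, omega_PC = 0, eta_1 = 0,
                      eta_2 = 0, eta_3 = 0, gamma_PC = 0, delta_1 = 0,
                      delta_2 = 0, delta_3 = 0.5, delta_4 = 0, h_CSC = 1,
                      h_PC = 0)
  d <- cscRhs(c(1, 0, 0, 1, 0), p2)
  expect_equal(d[1], 1)
  expect_equal(d[4], -0.5)
  expect_error(cscRhs(c(1, 2, 3), p0), "length 5")
})

test_that("parameter validation enforces the admissible domain", {
  expect_error(cscParameters(P_sy = 1.2), "P_sy")
  expect_error(cscParameters(delta_1 = -0.1), "non-negative")
  expect_error(cscParameters(0.5), "named")
  expect_error(cscParameters(bogus = 1), "unknown")
})

test_that("analytic Jacobian agrees with finite differences", {
  p <- cscParameters()
  zero <- rep(0, 5)
  J0 <- cscJacobian(zero, p)
  expect_equal(J0["N_CSC", "N_CSC"],
               p[["P_sy"]] * p[["omega_CSC"]] - p[["eta_1"]] - p[["delta_1"]])
  expect_equal(J0["N_CSC", "N_PC1"], p[["gamma_PC"]])
  # feedback terms vanish at the origin: they are proportional to the cell
  # counts even with h_CSC > 0
  expect_equal(J0["N_CSC", "N_TC"], 0)

  for (s in 1:20) {
    pr <- randomCscParameters(s)
    st <- randomCscState(1000 + s)
    J <- cscJacobian(st, pr)
    Jfd <- fdOracle(function(x) cscRhs(x, pr), st)
    expect_equal(unname(J), Jfd, tolerance = 1e-6)
  }
})

test_that("trajectories stay non-negative and DC is monotone without lysis", {
  g <- shortGrid(100, 51)
  for (s in 1:6) {
    pr <- randomCscParameters(100 + s)
    sim <- simulateOne(cscModel(pr), y0 = cscInitialState(), grid = g)
    expect_true(sim$success)
    expect_true(min(sim$trace) >= -10 * 1e-10)

    pr0 <- unclass(pr); pr0[["delta_4"]] <- 0
    sim0 <- simulateOne("csc", params = pr0, y0 = cscInitialState(), grid = g)
    expect_true(all(diff(sim0$trace[, "N_DC"]) >= -1e-8))
  }
})

test_that("fixture models behave as designed", {
  logi <- fixtureModel("logistic")
  sim <- simulateOne(logi, grid = shortGrid(50, 11))
  expect_equal(unname(sim$trace[11, 1]), 100, tolerance = 1e-6)

  bi <- fixtureModel("bistable_toy")
  rhs <- function(x, p) bi$rhs(x, c(p = p), 0)
  for (p in c(0.3, 0.7)) {
    expect_equal(rhs(0, p), 0)
    expect_equal(rhs(p, p), 0)
    expect_equal(rhs(1, p), 0)
  }

  mono <- fixtureModel("monotone_linear")
  # with a = (1, 0, 0) the relaxed output is rank-identical to x1
  set.seed(4)
  x1 <- runif(20)
  out <- vapply(x1, function(v) {
    s <- simulateOne(mono, params = c(x1 = v, x2 = runif(1), x3 = runif(1),
                                      a1 = 1, a2 = 0, a3 = 0),
                     grid = shortGrid(5, 6))
    s$trace[6, 1]
  }, numeric(1))
  expect_equal(rank(out), rank(x1))

  expect_error(fixtureModel("nope"), "logistic, monotone_linear, bistable_toy")
})

test_that("model definitions validate their contracts", {
  expect_error(
    modelDefinition("bad", c("a", "b"), "p",
                    rhs = function(state, params, t) 1,
                    default_parameters = c(p = 1),
                    default_initial_state = c(a = 0, b = 0)),
    "does not match")
  m <- getModel("logistic")
  expect_s3_class(m, "modelDefinition")
  expect_identical(getModel(m), m)
})
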