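test_that("Newton polishing finds known equilibria", {
  eq <- findEquilibrium("logistic", guess = c(N = 50))
  expect_true(eq$found)
  expect_equal(unname(eq$state), 100, tolerance = 1e-8)

  zero <- c(N_CSC = 0, N_PC1 = 0, N_PC2 = 0, N_TC = 0, N_DC = 0)
  eq0 <- findEquilibrium("csc", guess = zero)
  expect_true(eq0$found)
  expect_equal(max(abs(eq0$state)), 0)

  bi <- fixtureModel("bistable_toy")
  roots <- vapply(c(-0.1, 0.4, 1.2), function(g) {
    findEquilibrium(bi, params = c(p = 0.3), guess = c(x = g))$state
  }, numeric(1))
  expect_equal(unname(roots), c(0, 0.3, 1), tolerance = 1e-8)
})

test_that("stability classification matches analytic eigenvalues", {
  st <- classifyStability("logistic", c(N = 100))
  expect_true(st$stable)
  expect_equal(st$max_re, -1)

  zero <- c(N_CSC = 0, N_PC1 = 0, N_PC2 = 0, N_TC = 0, N_DC = 0)
  for (s in 1:10) {
    p <- randomCscParameters(200 + s, gamma_PC = 0)
    pstar <- invasionThreshold(p)
    below <- unclass(p); below[["P_sy"]] <- pstar * 0.8
    above <- unclass(p); above[["P_sy"]] <- min(1, pstar * 1.2)
    expect_true(classifyStability("csc", zero, below)$stable)
    expect_false(classifyStability("csc", zero, above)$stable)
    # with gamma_PC = 0 the leading eigenvalue at the origin is exactly the
    # CSC net growth rate
    expect_equal(classifyStability("csc", zero, above)$max_re,
                 above[["P_sy"]] * above[["omega_CSC"]] -
                   above[["eta_1"]] - above[["delta_1"]])
  }
})

test_that("the invasion boundary follows the closed form", {
  p <- cscParameters(eta_1 = 0.01, delta_1 = 0.015, omega_CSC = 1,
                     gamma_PC = 0)
  expect_equal(invasionThreshold(p), 0.025)
  expect_equal(invasionThreshold(cscParameters(eta_1 = 0, delta_1 = 0,
                                               gamma_PC = 0)), 0)
  expect_error(invasionThreshold(cscParameters(omega_CSC = 0)), "undefined")
  expect_warning(invasionThreshold(cscParameters(gamma_PC = 0.01)),
                 "de-differentiation")
})

test_that("the bistable fixture scan reports three branches with correct stability", {
  bi <- fixtureModel("bistable_toy")
  diag <- scanParameter(bi, name = "p", range = c(0.1, 0.9), n_points = 17,
                        y0 = c(x = 0.6),
                        extra_seeds = list(middle = c(x = 0.1)))
  expect_length(diag$transcritical_points, 0)
  b <- diag$branches
  triv <- b[b$branch == "trivial", ]
  expect_true(all(triv$stable))            # x = 0, eigenvalue -p < 0
  expect_equal(max(abs(triv$x)), 0)
  non <- b[b$branch == "nontrivial", ]
  expect_equal(non$x, rep(1, nrow(non)), tolerance = 1e-8)
  expect_true(all(non$stable))             # x = 1, eigenvalue p - 1 < 0
  mid <- b[b$branch == "middle", ]
  expect_equal(mid$x, mid$parameter_value, tolerance = 1e-6)
  expect_true(all(!mid$stable))            # x = p, eigenvalue p(1 - p) > 0
})

test_that("CSC scans locate the transcritical point at the closed form", {
  for (s in 1:5) {
    p <- randomCscParameters(300 + s, gamma_PC = 0)
    pstar <- invasionThreshold(p)
    diag <- scanParameter("csc", unclass(p), name = "P_sy",
                          range = c(0, 1), n_points = 21,
                          y0 = cscInitialState())
    expect_length(diag$transcritical_points, 1)
    expect_equal(diag$transcritical_points, pstar, tolerance = 1e-4)

    # stability exchange across the crossing
    b <- diag$branches
    triv <- b[b$branch == "trivial", ]
    expect_true(all(triv$stable[triv$parameter_value < pstar - 1e-3]))
    expect_true(all(!triv$stable[triv$parameter_value > pstar + 1e-3]))
    non <- b[b$branch == "nontrivial", ]
    up <- non[non$parameter_value > pstar + 0.05, ]
    expect_true(nrow(up) > 0)
    expect_true(all(up$stable))
    # the feedback bounds growth: the positive branch stays finite/positive
    expect_true(all(is.finite(as.matrix(up[, c("N_CSC", "N_PC1", "N_PC2",
                                               "N_TC", "N_DC")]))))
    expect_true(all(up$N_CSC > 0))
  }
})

test_that("trajectories agree with the invasion boundary on both sides", {
  small <- c(N_CSC = 10, N_PC1 = 0, N_PC2 = 0, N_TC = 0, N_DC = 0)
  for (s in 1:10) {
    p <- randomCscParameters(400 + s, gamma_PC = 0)
    pstar <- invasionThreshold(p)
    # at a 10% margin the CSC net rate is 0.1 * (eta_1 + delta_1); pick the
    # horizon so the linearized decay/growth factor is e^10
    horizon <- 10 / (0.1 * (p[["eta_1"]] + p[["delta_1"]]))
    g <- timeGrid(0, horizon, points = 21)
    below <- unclass(p); below[["P_sy"]] <- pstar * 0.9
    sim <- simulateOne("csc", below, small, g)
    expect_true(sim$success)
    expect_lt(sim$trace[21, "N_CSC"], 1e-2)
    above <- unclass(p); above[["P_sy"]] <- min(1, pstar * 1.1)
    sim2 <- simulateOne("csc", above, small, g)
    final <- sim2$trace[21, ]
    # the trajectory settles on the positive branch: polishing the final
    # state yields a nonzero equilibrium close to the trajectory's endpoint
    eq <- findEquilibrium("csc", above, final)
    expect_true(eq$found)
    expect_gt(eq$state[["N_CSC"]], 0)
    expect_equal(unname(final["N_CSC"]), eq$state[["N_CSC"]],
                 tolerance = 0.05)
  }
})

test_that("diagram rows satisfy the equilibrium condition independently", {
  p <- cscParameters(gamma_PC = 0)
  diag <- scanParameter("csc", unclass(p), name = "P_sy", range = c(0, 1),
                        n_points = 11, y0 = cscInitialState())
  b <- diag$branches
  states <- as.matrix(b[, c("N_CSC", "N_PC1", "N_PC2", "N_TC", "N_DC")])
  for (i in seq_len(nrow(b))) {
    pp <- unclass(p); pp[["P_sy"]] <- b$parameter_value[i]
    resid <- max(abs(cscRhs(states[i, ], pp)))
    expect_lt(resid, 1e-8 * max(1, max(abs(states[i, ]))))
  }
  f <- withr::local_tempfile(fileext = ".csv")
  writeDiagram(diag, f)
  expect_true(nrow(read.csv(f)) == nrow(b))
  expect_s3_class(plotDiagram(diag, "N_CSC"), "ggplot")
})
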