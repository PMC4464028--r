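test_that("equal-width partitions reproduce the published color codes", {
  # serum row: interior boundaries at quarter points of [0.01, 5.99]
  serum <- partitionRange(0.01, 5.99, 4)
  expect_equal(serum$boundaries, c(1.505, 3.000, 4.495))
  psy <- partitionRange(0, 1, 4)
  expect_equal(psy$boundaries, c(0.25, 0.50, 0.75))
  expect_equal(levelLabels(psy),
               c("[0.00, 0.25]", "(0.25, 0.50]", "(0.50, 0.75]",
                 "(0.75, 1.00]"))
  expect_equal(psy$colors, c("black", "blue", "red", "green"))
  expect_error(partitionRange(3, 3, 4), "min < max")
  expect_error(partitionRange(0, 1, 1), "r = 2")
})

test_that("level widths are equal to machine precision for any r", {
  for (r in c(2, 4, 7, 13)) {
    part <- partitionRange(-2.3, 11.7, r)
    w <- diff(c(part$min, part$boundaries, part$max))
    expect_lt(max(w) - min(w), 1e-12 * (part$max - part$min))
  }
})

test_that("level assignment follows the bracket convention", {
  part <- partitionRange(0, 1, 4)
  expect_equal(assignLevel(c(0, 0.25, 0.250001, 0.75, 0.750001, 1), part),
               c(1L, 1L, 2L, 3L, 4L, 4L))
  expect_error(assignLevel(1.01, part), "outside")
  expect_error(assignLevel(-0.001, part), "outside")
  # monotone in the value, every in-range value maps to exactly one level
  set.seed(3)
  v <- sort(runif(100))
  lv <- assignLevel(v, part)
  expect_true(all(diff(lv) >= 0))
  expect_true(all(lv >= 1 & lv <= 4))
})

test_that("combination expressions evaluate row-wise under the restricted grammar", {
  d <- data.frame(P_sy = c(0.5, 1), omega_CSC = c(0.5, 2), eta_1 = c(0, 0.5))
  expect_equal(combineColumns("P_sy*omega_CSC", d), c(0.25, 2))
  expect_equal(combineColumns("P_sy*omega_CSC-eta_1", d), c(0.25, 1.5))
  expect_equal(combineColumns("(P_sy + eta_1) * 2", d), c(1, 3))
  expect_error(combineColumns("P_sy/omega_CSC", d), "not allowed")
  expect_error(combineColumns("P_sy^2", d), "not allowed")
  expect_error(combineColumns("P_sy * missing_one", d), "unknown identifier")
})

test_that("colored traces draw every sample in its level color", {
  # 8 samples, 2 per level, on the logistic fixture
  key <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.95)
  d <- structure(list(matrix = data.frame(r = key + 0.5), n = 8L, seed = 1L,
                      specs = list()), class = "sampleDesign")
  Y <- simulateEnsemble("logistic", d$matrix, grid = shortGrid(10, 6))
  part <- partitionRange(0, 1, 4, parameter = "key")
  g <- coloredTraces(Y, key, part, "N")
  built <- ggplot2::ggplot_build(g)
  drawn <- built$data[[1]]
  # 8 polylines, colors partitioned 2/2/2/2
  expect_equal(length(unique(drawn$group)), 8)
  cols <- tapply(drawn$colour, drawn$group, unique)
  expect_equal(as.vector(sort(table(unlist(cols)))), c(2, 2, 2, 2))
  expect_setequal(unique(unlist(cols)), c("black", "blue", "red", "green"))
  # legend keeps all four interval entries even when some levels are empty
  one_level <- coloredTraces(Y, rep(0.1, 8), part, "N")
  expect_equal(levels(one_level$data$level), levelLabels(part))
  sc <- attr(g, "sidecar")
  expect_equal(sc$counts_per_level, c(2, 2, 2, 2))
})

test_that("colored scatters accept derived columns and record sidecars", {
  d <- data.frame(a = runif(12), b = runif(12))
  Y <- simulateEnsemble("monotone_linear",
                        stats::setNames(d, c("x1", "x2")),
                        grid = shortGrid(5, 6))
  sl <- outputsAtTime(Y, 5)
  derived <- combineColumns("a*b", d)
  part <- partitionRange(min(derived), max(derived), 4, parameter = "a*b")
  g <- coloredScatter(sl, derived, part, "y")
  built <- ggplot2::ggplot_build(g)
  expect_equal(nrow(built$data[[1]]), 12)
  sc <- attr(g, "sidecar")
  expect_equal(sum(sc$counts_per_level), 12)
  expect_equal(sc$time, 5)
  expect_error(coloredScatter(sl, derived, part, "bogus"), "unknown variable")
})

test_that("log-scale floors non-positive values and counts them", {
  key <- c(0.2, 0.8)
  m <- data.frame(r = c(1, 1))
  Y <- simulateEnsemble("logistic", m, y0 = c(N = 0), grid = shortGrid(5, 4))
  part <- partitionRange(0, 1, 4)
  g <- coloredTraces(Y, key, part, "N", scale = "log", log_floor = 1e-3)
  sc <- attr(g, "sidecar")
  expect_equal(sc$clipped_points, 8L)  # all values of both flat-zero traces
})

test_that("figures save with machine-checkable sidecars", {
  key <- c(0.2, 0.8, 0.4)
  m <- data.frame(r = c(0.9, 1, 1.1))
  Y <- simulateEnsemble("logistic", m, grid = shortGrid(5, 4))
  part <- partitionRange(0, 1, 4, parameter = "r scaled")
  g <- coloredTraces(Y, key, part, "N")
  dir <- withr::local_tempdir()
  files <- saveFigure(g, file.path(dir, "fig"), formats = "png")
  expect_true(file.exists(file.path(dir, "fig.png")))
  side <- jsonlite::read_json(file.path(dir, "fig.json"))
  expect_equal(unlist(side$bounds), c(0, 0.25, 0.5, 0.75, 1))
})
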