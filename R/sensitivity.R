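#' Rank-transform a column
#'
#' Ranks `1..n` with ties given the average of the ranks they cover (the
#' convention of the standard LHS/PRCC methodology). An all-constant column
#' is flagged degenerate via the `"degenerate"` attribute: partial rank
#' correlation is undefined for it.
#'
#' @param x Numeric vector, length `>= 2`.
#' @return Numeric vector of ranks, with attribute `degenerate`.
#' @export
#' @examples
#' rankTransform(c(3.2, 1.1, 2.7)) # 3 1 2
#' rankTransform(c(5, 5, 1))       # 2.5 2.5 1
rankTransform <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  r <- rank(x, ties.method = "average")
  attr(r, "degenerate") <- length(unique(x)) == 1L
  r
}

#' Partial rank correlation coefficients with significance tests
#'
#' For each parameter j, all design columns and the output are
#' rank-transformed; the ranks of column j and of the output are each
#' residualized (least squares, with intercept) on the ranks of the other
#' `k - 1` parameters, and PRCC_j is the Pearson correlation of the two
#' residual vectors. Significance uses
#' `t = PRCC * sqrt((n - 2 - p) / (1 - PRCC^2))` with `p = k - 1`
#' conditioning variables, against a two-sided Student-t with `n - 2 - p`
#' degrees of freedom.
#'
#' @param X Numeric `n x k` design matrix (or data frame) of sampled
#'   parameters.
#' @param y Numeric output vector of length n.
#' @return List with `prcc` and `pvalue` (named length-k vectors), `n`,
#'   `k`, and `df` (`n - 2 - (k - 1)`). When `y` is constant the
#'   coefficients are all `NA` with a warning.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= k + 1) {
    stop("need n > k + 1 samples for PRCC (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  df <- n - 2 - (k - 1)
  ry <- rankTransform(y)
  if (attr(ry, "degenerate")) {
    warning("output is constant across samples; PRCC undefined",
            call. = FALSE)
    na <- stats::setNames(rep(NA_real_, k), nms)
    return(list(prcc = na, pvalue = na, n = n, k = k, df = df))
  }
  R <- matrix(0, n, k)
  for (j in seq_len(k)) {
    rj <- rankTransform(X[, j])
    if (attr(rj, "degenerate")) {
      stop("design column '", nms[j], "' is constant; PRCC undefined for it",
           call. = FALSE)
    }
    R[, j] <- rj
  }
  coef <- pval <- stats::setNames(rep(NA_real_, k), nms)
  for (j in seq_len(k)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      stop("rank-deficient residualization: collinear rank columns among {",
           paste(nms[-j], collapse = ", "), "}", call. = FALSE)
    }
    res_x <- stats::setNames(qr.resid(qrz, R[, j]), NULL)
    res_y <- stats::setNames(qr.resid(qrz, as.numeric(ry)), NULL)
    r <- sum(res_x * res_y) / sqrt(sum(res_x^2) * sum(res_y^2))
    r <- max(-1, min(1, r))
    coef[j] <- r
    pval[j] <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt(df / (1 - r^2))
      2 * stats::pt(-abs(tstat), df)
    }
  }
  list(prcc = coef, pvalue = pval, n = n, k = k, df = df)
}

#' Critical PRCC magnitude at a significance level
#'
#' The |PRCC| below which the two-sided t-test is not significant at level
#' `alpha`: `t_crit / sqrt(t_crit^2 + df)` with `df = n - 2 - (k - 1)`.
#' Used to shade the non-significant band in time-course plots.
#'
#' @param n Sample size; `k` number of parameters; `alpha` level.
#' @return Critical |PRCC| value.
#' @export
prccCritical <- function(n, k, alpha = 0.01) {
  df <- n - 2 - (k - 1)
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

#' Time-course PRCC between a design and an ensemble
#'
#' Applies [prcc()] at every grid time and output variable, using only the
#' rows whose simulations succeeded (listwise exclusion). Time points where
#' an output is constant across samples (typically `t = 0` with a shared
#' initial state) yield `NA` coefficients and are flagged, not errors.
#'
#' @param design A [lhsSample()] design.
#' @param Y A matching [simulateEnsemble()] output.
#' @param alpha Significance level (default 0.01).
#' @param stride Evaluate every `stride`-th grid time (default 1 = all).
#' @return Object of class `sensitivityResult`: arrays `prcc` and `pvalue`
#'   (`m x k x v`), `times`, `parameters`, `variables`, `n_effective`,
#'   `alpha`, and `r_crit` (per-time critical |PRCC|).
#' @export
prccOverTime <- function(design, Y, alpha = 0.01, stride = 1L) {
  stopifnot(inherits(design, "sampleDesign"), inherits(Y, "ensembleOutput"))
  keep <- Y$success
  n_eff <- sum(keep)
  X <- as.matrix(design$matrix[keep, , drop = FALSE])
  k <- ncol(X)
  if (n_eff < k + 2) {
    stop("only ", n_eff, " surviving rows; need at least k + 2 = ", k + 2,
         call. = FALSE)
  }
  jt <- seq(1, length(Y$grid$times), by = stride)
  times <- Y$grid$times[jt]
  vars <- Y$variable_names
  m <- length(jt)
  co <- array(NA_real_, dim = c(m, k, length(vars)),
              dimnames = list(NULL, colnames(X), vars))
  pv <- co

  # The design ranks (and hence the residualizing projections for each
  # parameter) are identical at every time point and output variable, so
  # the per-parameter QR decompositions are factored once and reused; only
  # the output ranks change across the time course.
  nms <- colnames(X)
  R <- matrix(0, n_eff, k)
  for (j in seq_len(k)) {
    rj <- rankTransform(X[, j])
    if (attr(rj, "degenerate")) {
      stop("design column '", nms[j], "' is constant; PRCC undefined for it",
           call. = FALSE)
    }
    R[, j] <- rj
  }
  qrs <- vector("list", k)
  res_x <- matrix(0, n_eff, k)
  for (j in seq_len(k)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qrs[[j]] <- qr(Z)
    if (qrs[[j]]$rank < ncol(Z)) {
      stop("rank-deficient residualization: collinear rank columns among {",
           paste(nms[-j], collapse = ", "), "}", call. = FALSE)
    }
    res_x[, j] <- qr.resid(qrs[[j]], R[, j])
  }
  ss_x <- colSums(res_x^2)
  df <- n_eff - 2 - (k - 1)
  for (ti in seq_len(m)) {
    for (v in seq_along(vars)) {
      yv <- Y$values[keep, jt[ti], v]
      if (length(unique(yv)) == 1L) next  # degenerate slice, stays NA
      ry <- rank(yv, ties.method = "average")
      for (j in seq_len(k)) {
        res_y <- qr.resid(qrs[[j]], ry)
        r <- sum(res_x[, j] * res_y) / sqrt(ss_x[j] * sum(res_y^2))
        r <- max(-1, min(1, r))
        co[ti, j, v] <- r
        pv[ti, j, v] <- if (abs(r) >= 1) 0 else {
          2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
        }
      }
    }
  }
  structure(list(prcc = co, pvalue = pv, times = times,
                 parameters = colnames(X), variables = vars,
                 n_effective = n_eff, alpha = alpha,
                 r_crit = rep(prccCritical(n_eff, k, alpha), m)),
            class = "sensitivityResult")
}

#' @export
print.sensitivityResult <- function(x, ...) {
  cat("<sensitivityResult> ", length(x$times), " times x ",
      length(x$parameters), " parameters x ", length(x$variables),
      " variables\n", sep = "")
  cat("  n_effective = ", x$n_effective, ", alpha = ", x$alpha,
      ", critical |PRCC| = ", signif(x$r_crit[1], 3), "\n", sep = "")
  # ranking at the final time, the equilibrium end of the course
  fin <- apply(abs(x$prcc[length(x$times), , , drop = FALSE]), 2, max,
               na.rm = TRUE)
  top <- sort(fin, decreasing = TRUE)[seq_len(min(5, length(fin)))]
  cat("  top |PRCC| at t = ", x$times[length(x$times)], ": ",
      paste(sprintf("%s = %.3f", names(top), top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Long-format table of a sensitivity result
#'
#' @param x A [prccOverTime()] result.
#' @param ... Unused.
#' @return Data frame with columns `time`, `parameter`, `variable`,
#'   `prcc`, `pvalue`.
#' @export
as.data.frame.sensitivityResult <- function(x, ...) {
  g <- expand.grid(time = x$times, parameter = x$parameters,
                   variable = x$variables, stringsAsFactors = FALSE)
  g$prcc <- as.vector(x$prcc)
  g$pvalue <- as.vector(x$pvalue)
  g
}

#' Write a sensitivity result as CSV + JSON
#'
#' @param result A [prccOverTime()] result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
writeSensitivity <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "prcc_long.csv")
  utils::write.csv(as.data.frame(result), csv, row.names = FALSE)
  peak <- apply(abs(result$prcc), 2, max, na.rm = TRUE)
  js <- file.path(dir, "prcc_summary.json")
  jsonlite::write_json(
    list(n_effective = result$n_effective, alpha = result$alpha,
         r_crit = result$r_crit[1],
         peak_abs_prcc = as.list(peak)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Time-course PRCC plot for one output variable
#'
#' One line per parameter with the non-significant band (|PRCC| below the
#' critical value) shaded yellow.
#'
#' @param result A [prccOverTime()] result.
#' @param variable Output variable name.
#' @param parameters Optional subset of parameters to draw.
#' @return A ggplot object.
#' @export
plotPrcc <- function(result, variable, parameters = NULL) {
  stopifnot(inherits(result, "sensitivityResult"))
  if (!variable %in% result$variables) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  d <- as.data.frame(result)
  d <- d[d$variable == variable, ]
  if (!is.null(parameters)) d <- d[d$parameter %in% parameters, ]
  band <- data.frame(xmin = min(result$times), xmax = max(result$times),
                     ymin = -result$r_crit[1], ymax = result$r_crit[1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$prcc,
                                  color = .data$parameter)) +
    ggplot2::geom_rect(data = band,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       inherit.aes = FALSE, fill = "yellow", alpha = 0.4) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "time", y = "PRCC",
                  title = paste0("PRCC over time: ", variable)) +
    ggplot2::theme_minimal()
}
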