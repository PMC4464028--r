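#' Closed-form tumor invasion boundary
#'
#' The trivial equilibrium (no tumor) loses stability when the probability
#' of symmetric CSC division exceeds
#' `P* = (eta_1 + delta_1) / omega_CSC`: below `P*` the CSC compartment's
#' net growth at low density is negative and the tumor dies out; above it
#' the tumor invades and stabilizes on the positive branch. The closed
#' form comes from the CSC row of the Jacobian at the origin and is exact
#' when there is no de-differentiation; with `gamma_PC > 0` the PC1
#' compartment feeds back into the CSC one and the true crossing shifts, so
#' a warning is attached (use [scanParameter()] for the numerically exact
#' crossing).
#'
#' @param params A [cscParameters()] vector.
#' @return `P*` (dimensionless); attribute `"approximate"` is `TRUE` when
#'   `gamma_PC > 0`.
#' @export
#' @examples
#' invasionThreshold(cscParameters()) # 0.025 at the default baselines
invasionThreshold <- function(params) {
  p <- checkNamedNumeric(unclass(params), cscParameterNames, "CSC parameters")
  if (p[["omega_CSC"]] == 0) {
    stop("invasion threshold undefined for omega_CSC = 0", call. = FALSE)
  }
  ps <- (p[["eta_1"]] + p[["delta_1"]]) / p[["omega_CSC"]]
  if (p[["gamma_PC"]] > 0) {
    warning("gamma_PC > 0: the closed form ignores de-differentiation; ",
            "the exact crossing may differ (see scanParameter)",
            call. = FALSE)
    attr(ps, "approximate") <- TRUE
  }
  ps
}

#' Find an equilibrium by damped Newton iteration
#'
#' Solves `rhs(state) = 0` starting from `guess`, using the model's
#' analytic Jacobian when available (finite differences otherwise) and
#' halving the step until the residual decreases. Non-convergence is a
#' structured not-found result, not an error.
#'
#' @param model A [modelDefinition()] or model name.
#' @param params Named parameter vector (defaults to the model's).
#' @param guess Initial state vector.
#' @param tol Residual tolerance, scaled by `max(1, ||state||)`.
#' @param max_iter Iteration cap.
#' @return List with `found` (logical), `state` (the root, or last
#'   iterate), `residual` (max-norm of `rhs` there).
#' @export
findEquilibrium <- function(model, params = NULL, guess,
                            tol = 1e-10, max_iter = 100L) {
  model <- getModel(model)
  if (is.null(params)) params <- model$default_parameters
  params <- checkNamedNumeric(params, model$parameter_names, "params")
  x <- checkNamedNumeric(guess, model$state_names, "guess")
  f <- model$rhs(x, params, 0)
  for (it in seq_len(max_iter)) {
    scale <- max(1, sqrt(sum(x^2)))
    if (max(abs(f)) <= tol * scale) {
      return(list(found = TRUE, state = x, residual = max(abs(f))))
    }
    J <- modelJacobian(model, x, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # singular Jacobian (e.g. a fold in the scalar field): fall back to a
      # Levenberg-Marquardt step
      tau <- 1e-6 * max(1, sum(abs(J)))
      step <- tryCatch(
        solve(crossprod(J) + tau * diag(ncol(J)), -crossprod(J, f)),
        error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        return(list(found = FALSE, state = x, residual = max(abs(f))))
      }
      step <- as.numeric(step)
      if (max(abs(step)) < 1e-12 * max(1, max(abs(x)))) {
        # stationary point of the residual norm that is not a root (e.g. the
        # vertex of the logistic parabola): nudge off it deterministically
        x <- x + 1e-3 * pmax(1, abs(x))
        f <- model$rhs(x, params, 0)
        next
      }
    }
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- model$rhs(xn, params, 0)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) {
      # stalled line search; accept the full step once in case we sit on a
      # plateau, otherwise report not-found
      xn <- x + step
      fn <- model$rhs(xn, params, 0)
      if (!all(is.finite(fn)) || max(abs(fn)) >= max(abs(f))) {
        return(list(found = FALSE, state = x, residual = max(abs(f))))
      }
    }
    x <- xn; f <- fn
  }
  scale <- max(1, sqrt(sum(x^2)))
  list(found = max(abs(f)) <= tol * scale, state = x,
       residual = max(abs(f)))
}

#' Classify the stability of an equilibrium
#'
#' Eigenvalues of the Jacobian at the equilibrium. Stable means all real
#' parts below `-tol_stab`; a leading real part within `tol_stab` of zero
#' is labeled marginal rather than forced into either class.
#'
#' @param model A [modelDefinition()] or model name.
#' @param equilibrium State vector at (or near) an equilibrium.
#' @param params Named parameter vector.
#' @param tol_stab Stability tolerance separating stable from marginal.
#' @return List with `max_re` (largest real part), `stable` (logical),
#'   `marginal` (logical), `eigenvalues`.
#' @export
classifyStability <- function(model, equilibrium, params = NULL,
                              tol_stab = 1e-9) {
  model <- getModel(model)
  if (is.null(params)) params <- model$default_parameters
  params <- checkNamedNumeric(params, model$parameter_names, "params")
  J <- modelJacobian(model, equilibrium, params)
  ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                 error = function(e) {
                   stop("eigendecomposition failed for Jacobian:\n",
                        paste(utils::capture.output(print(J)), collapse = "\n"),
                        call. = FALSE)
                 })
  max_re <- max(Re(ev))
  list(max_re = max_re,
       stable = max_re < -tol_stab,
       marginal = abs(max_re) <= tol_stab,
       eigenvalues = ev)
}

# Leading eigenvalue of the Jacobian at the polished trivial equilibrium,
# as a function of one parameter; used to refine transcritical crossings.
leadingEigAt <- function(model, params, name, value, origin) {
  params[name] <- value
  eq <- findEquilibrium(model, params, origin)
  classifyStability(model, eq$state, params)$max_re
}

#' One-parameter bifurcation scan with transcritical detection
#'
#' Scans `name` over a grid, tracking two equilibrium branches: the trivial
#' branch polished from the origin, and a nontrivial branch continued by
#' Newton from the previous grid value. The nontrivial branch is seeded by
#' a long transient simulation; because a positive attractor typically
#' exists only on one side of the transcritical point, the seed simulation
#' is attempted at both ends of the scan and continuation proceeds from
#' whichever end yields a nonzero attractor. Sign changes of the trivial
#' branch's leading eigenvalue are refined by bisection to `refine_tol` in
#' the parameter.
#'
#' @param model A [modelDefinition()] or model name.
#' @param params Named parameter vector (defaults to the model's); the
#'   scanned entry is overwritten at each grid value.
#' @param name Scanned parameter name.
#' @param range Numeric `c(lo, hi)`.
#' @param n_points Grid size, `>= 3`.
#' @param y0 Initial state for the seed simulation (defaults to the
#'   model's).
#' @param extra_seeds Optional named list of state vectors; each is polished
#'   and continued across the grid as an additional branch (useful to track
#'   unstable branches a transient simulation cannot reach).
#' @param refine_tol Bisection tolerance on the crossing parameter value.
#' @return Object of class `bifurcationDiagram`: `parameter`, `grid`,
#'   `branches` (data frame: parameter value, branch id, state components,
#'   leading eigenvalue, stable/marginal flags), and
#'   `transcritical_points` (numeric vector of refined crossings).
#' @export
scanParameter <- function(model, params = NULL, name, range, n_points = 51L,
                          y0 = NULL, extra_seeds = NULL, refine_tol = 1e-6) {
  model <- getModel(model)
  if (is.null(params)) params <- model$default_parameters
  params <- checkNamedNumeric(params, model$parameter_names, "params")
  if (!name %in% model$parameter_names) {
    stop("'", name, "' is not a parameter of model '", model$name, "'",
         call. = FALSE)
  }
  stopifnot(length(range) == 2L, range[1] < range[2], n_points >= 3L)
  if (is.null(y0)) y0 <- model$default_initial_state
  grid <- seq(range[1], range[2], length.out = n_points)
  origin <- stats::setNames(rep(0, length(model$state_names)),
                            model$state_names)

  rows <- list()
  addRow <- function(pval, branch, state, stab) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter_value = pval, branch = branch,
      t(stats::setNames(state, model$state_names)),
      max_re = stab$max_re, stable = stab$stable,
      marginal = stab$marginal)
  }

  # trivial branch
  triv_maxre <- numeric(n_points)
  for (i in seq_len(n_points)) {
    p <- params; p[name] <- grid[i]
    eq <- findEquilibrium(model, p, origin)
    st <- classifyStability(model, eq$state, p)
    triv_maxre[i] <- st$max_re
    addRow(grid[i], "trivial", eq$state, st)
  }

  # nontrivial branch: seed by long transient simulation at either end
  seedState <- function(pval) {
    p <- params; p[name] <- pval
    dr <- p[grepl("^delta", names(p))]
    horizon <- if (length(dr) && min(dr[dr > 0]) > 0) {
      10 / min(dr[dr > 0])
    } else 100
    sim <- simulateOne(model, p, y0, timeGrid(0, horizon, points = 11),
                       rtol = 1e-8, atol = 1e-10)
    if (!sim$success) return(NULL)
    final <- sim$trace[nrow(sim$trace), ]
    eq <- findEquilibrium(model, p, final)
    if (!eq$found) NULL else eq$state
  }
  order_idx <- seq_len(n_points)
  seed <- seedState(grid[1])
  if (is.null(seed) || sqrt(sum(seed^2)) < 1e-6) {
    seed2 <- seedState(grid[n_points])
    if (!is.null(seed2) && sqrt(sum(seed2^2)) >= 1e-6) {
      seed <- seed2
      order_idx <- rev(order_idx)
    }
  }
  if (!is.null(seed)) {
    current <- seed
    for (i in order_idx) {
      p <- params; p[name] <- grid[i]
      eq <- findEquilibrium(model, p, current)
      if (!eq$found) {
        message("nontrivial branch lost at ", name, " = ", grid[i],
                "; branch truncated")
        break
      }
      current <- eq$state
      st <- classifyStability(model, current, p)
      addRow(grid[i], "nontrivial", current, st)
    }
  }

  # user-supplied additional branches (e.g. unstable interior branches)
  if (!is.null(extra_seeds)) {
    for (bi in seq_along(extra_seeds)) {
      bname <- names(extra_seeds)[bi]
      if (is.null(bname) || !nzchar(bname)) bname <- paste0("extra", bi)
      current <- checkNamedNumeric(extra_seeds[[bi]], model$state_names,
                                   "extra seed")
      for (i in seq_len(n_points)) {
        p <- params; p[name] <- grid[i]
        eq <- findEquilibrium(model, p, current)
        if (!eq$found) {
          message("branch '", bname, "' lost at ", name, " = ", grid[i])
          break
        }
        current <- eq$state
        st <- classifyStability(model, current, p)
        addRow(grid[i], bname, current, st)
      }
    }
  }

  # transcritical candidates: leading eigenvalue of the trivial branch
  # changes sign between grid neighbours; refine by bisection
  crossings <- numeric(0)
  for (i in seq_len(n_points - 1)) {
    a <- triv_maxre[i]; b <- triv_maxre[i + 1]
    if (is.finite(a) && is.finite(b) && a * b < 0) {
      lo <- grid[i]; hi <- grid[i + 1]; fa <- a
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        fm <- leadingEigAt(model, params, name, mid, origin)
        if (fa * fm <= 0) hi <- mid else { lo <- mid; fa <- fm }
      }
      crossings <- c(crossings, (lo + hi) / 2)
    }
  }

  branches <- do.call(rbind, rows)
  structure(list(parameter = name, grid = grid, branches = branches,
                 transcritical_points = crossings),
            class = "bifurcationDiagram")
}

#' @export
print.bifurcationDiagram <- function(x, ...) {
  cat("<bifurcationDiagram> parameter ", x$parameter, " over [",
      min(x$grid), ", ", max(x$grid), "], ", length(x$grid), " points\n",
      sep = "")
  tab <- table(x$branches$branch)
  cat("  branches: ", paste(sprintf("%s (%d pts)", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
  if (length(x$transcritical_points)) {
    cat("  transcritical point(s) at ",
        paste(signif(x$transcritical_points, 6), collapse = ", "), "\n",
        sep = "")
  } else cat("  no transcritical point detected in range\n")
  invisible(x)
}

#' Write a bifurcation diagram as CSV
#'
#' @param diagram A [scanParameter()] result.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeDiagram <- function(diagram, path) {
  stopifnot(inherits(diagram, "bifurcationDiagram"))
  utils::write.csv(diagram$branches, path, row.names = FALSE)
  invisible(path)
}

#' Branch plot of a bifurcation diagram
#'
#' Solid lines for stable branch segments, dashed for unstable; detected
#' transcritical points marked by vertical dotted lines.
#'
#' @param diagram A [scanParameter()] result.
#' @param variable State component for the y axis (default the first).
#' @return A ggplot object.
#' @export
plotDiagram <- function(diagram, variable = NULL) {
  b <- diagram$branches
  states <- setdiff(colnames(b),
                    c("parameter_value", "branch", "max_re", "stable",
                      "marginal"))
  if (is.null(variable)) variable <- states[1]
  if (!variable %in% states) stop("unknown state '", variable, "'",
                                  call. = FALSE)
  d <- data.frame(p = b$parameter_value, y = b[[variable]],
                  branch = b$branch,
                  stability = ifelse(b$stable, "stable", "unstable"))
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$y,
                                       group = interaction(.data$branch,
                                                           .data$stability),
                                       color = .data$branch,
                                       linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = diagram$parameter, y = variable) +
    ggplot2::theme_minimal()
  for (pc in diagram$transcritical_points) {
    g <- g + ggplot2::geom_vline(xintercept = pc, linetype = "dotted")
  }
  g
}
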