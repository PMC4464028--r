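#' Time grid for ensemble simulation
#'
#' @param t_ini,t_end Interval endpoints, `t_ini < t_end`.
#' @param points Number of grid points for a uniform grid (including both
#'   endpoints), `>= 2`.
#' @param times Explicit strictly increasing vector of sample times
#'   (overrides `points`); must start at `t_ini` and end at `t_end`.
#' @return An object of class `timeGrid` with elements `t_ini`, `t_end`,
#'   `times`.
#' @export
#' @examples
#' timeGrid(0, 200, points = 200)
timeGrid <- function(t_ini, t_end, points = NULL, times = NULL) {
  stopifnot(is.numeric(t_ini), is.numeric(t_end))
  if (t_ini >= t_end) stop("t_ini must be < t_end", call. = FALSE)
  if (is.null(times)) {
    if (is.null(points) || points < 2) {
      stop("'points' must be >= 2 when 'times' is not given", call. = FALSE)
    }
    times <- seq(t_ini, t_end, length.out = points)
  } else {
    if (any(diff(times) <= 0)) {
      stop("'times' must be strictly increasing", call. = FALSE)
    }
    if (times[1] != t_ini || times[length(times)] != t_end) {
      stop("'times' must include both endpoints", call. = FALSE)
    }
  }
  structure(list(t_ini = t_ini, t_end = t_end, times = times),
            class = "timeGrid")
}

#' Integrate a model once over a time grid
#'
#' Solves the model with a stiff-capable implicit-switching integrator
#' (`deSolve::lsoda`, using the model's analytic Jacobian when present) and
#' returns the solution at exactly the grid times. Integration failures are
#' returned as structured results, not raised, so that batch runs survive
#' pathological parameter draws.
#'
#' @param model A [modelDefinition()] or model name (see [getModel()]).
#' @param params Named parameter vector (defaults to the model's).
#' @param y0 Initial state (defaults to the model's).
#' @param grid A [timeGrid()].
#' @param rtol,atol Relative / absolute solver tolerances.
#' @return List with `success` (logical), `trace` (an `m x v` matrix,
#'   `NULL` on failure), and `reason` (`NA` or a failure message).
#' @export
simulateOne <- function(model, params = NULL, y0 = NULL, grid,
                        rtol = 1e-8, atol = 1e-10) {
  model <- getModel(model)
  stopifnot(inherits(grid, "timeGrid"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  if (is.null(params)) params <- model$default_parameters
  params <- checkNamedNumeric(params, model$parameter_names, "params")
  if (is.null(y0)) y0 <- model$default_initial_state
  y0 <- checkNamedNumeric(y0, model$state_names, "y0")

  func <- function(t, y, p) list(model$rhs(y, p, t))
  jacfunc <- if (!is.null(model$jacobian)) {
    function(t, y, p) model$jacobian(y, p)
  }
  res <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = y0, times = grid$times, func = func, parms = params,
      method = "lsoda", rtol = rtol, atol = atol,
      jacfunc = jacfunc, jactype = if (is.null(jacfunc)) "fullint" else "fullusr",
      maxsteps = 50000)),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(list(success = FALSE, trace = NULL, reason = conditionMessage(res)))
  }
  trace <- unname(as.matrix(res)[, -1, drop = FALSE])
  if (nrow(trace) != length(grid$times) || any(!is.finite(trace))) {
    return(list(success = FALSE, trace = NULL,
                reason = "integration incomplete or non-finite"))
  }
  colnames(trace) <- model$state_names
  list(success = TRUE, trace = trace, reason = NA_character_)
}

#' Simulate a model over every row of a design
#'
#' Runs [simulateOne()] once per design row and assembles the output matrix
#' Y: an `n x m x v` array of model outputs (samples x times x variables).
#' Parameters absent from the design take the model's defaults. Failed
#' rows are flagged and excluded from downstream statistics; they abort the
#' run only when more than half of the rows fail.
#'
#' @param model A [modelDefinition()] or model name.
#' @param design A [lhsSample()] design (or a bare data frame of parameter
#'   columns).
#' @param y0 Initial state (defaults to the model's).
#' @param grid A [timeGrid()].
#' @param rtol,atol Solver tolerances, as in [simulateOne()].
#' @return An object of class `ensembleOutput`: `grid`, `variable_names`,
#'   `values` (n x m x v array), `success` (logical n), `failure_log`
#'   (data frame of row/reason).
#' @export
simulateEnsemble <- function(model, design, y0 = NULL, grid,
                             rtol = 1e-8, atol = 1e-10) {
  model <- getModel(model)
  m <- if (inherits(design, "sampleDesign")) design$matrix else design
  stopifnot(is.data.frame(m), nrow(m) >= 1L)
  unknown <- setdiff(colnames(m), model$parameter_names)
  if (length(unknown)) {
    stop("design column(s) not among model parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(m)
  nt <- length(grid$times)
  v <- length(model$state_names)
  values <- array(NA_real_, dim = c(n, nt, v),
                  dimnames = list(NULL, NULL, model$state_names))
  success <- logical(n)
  fail_row <- integer(0); fail_reason <- character(0)
  base <- model$default_parameters
  for (i in seq_len(n)) {
    p <- base
    p[colnames(m)] <- as.numeric(m[i, ])
    one <- simulateOne(model, p, y0, grid, rtol = rtol, atol = atol)
    success[i] <- one$success
    if (one$success) {
      values[i, , ] <- one$trace
    } else {
      fail_row <- c(fail_row, i)
      fail_reason <- c(fail_reason, one$reason)
    }
  }
  if (sum(!success) > n / 2) {
    stop(sum(!success), "/", n, " simulations failed; review solver ",
         "tolerances and parameter ranges", call. = FALSE)
  }
  if (length(fail_row)) {
    message(length(fail_row), "/", n,
            " simulations failed and are excluded from statistics")
  }
  structure(list(grid = grid,
                 variable_names = model$state_names,
                 values = values,
                 success = success,
                 failure_log = data.frame(row = fail_row,
                                          reason = fail_reason)),
            class = "ensembleOutput")
}

#' @export
print.ensembleOutput <- function(x, ...) {
  d <- dim(x$values)
  cat("<ensembleOutput> ", d[1], " samples x ", d[2], " times x ", d[3],
      " variables (", paste(x$variable_names, collapse = ", "), ")\n",
      sep = "")
  cat("  time interval [", x$grid$t_ini, ", ", x$grid$t_end, "], ",
      sum(x$success), "/", d[1], " successful runs\n", sep = "")
  invisible(x)
}

#' Slice an ensemble at one time point
#'
#' @param Y An [simulateEnsemble()] output.
#' @param t Requested time, within the grid range.
#' @param snap If `FALSE` (default), `t` must match a grid time exactly
#'   (within machine rounding); if `TRUE`, the nearest grid time is used
#'   and reported via the `"time"` attribute.
#' @return `n x v` matrix of outputs at the chosen time, with attribute
#'   `"time"` set to the grid time actually used.
#' @export
outputsAtTime <- function(Y, t, snap = FALSE) {
  stopifnot(inherits(Y, "ensembleOutput"))
  times <- Y$grid$times
  if (t < Y$grid$t_ini || t > Y$grid$t_end) {
    stop("t = ", t, " outside the grid range [", Y$grid$t_ini, ", ",
         Y$grid$t_end, "]", call. = FALSE)
  }
  j <- which.min(abs(times - t))
  if (!snap && abs(times[j] - t) > 1e-9 * max(1, abs(t))) {
    stop("t = ", t, " is not a grid time (nearest: ", times[j],
         "); use snap = TRUE to snap", call. = FALSE)
  }
  out <- Y$values[, j, , drop = FALSE]
  dim(out) <- dim(Y$values)[c(1, 3)]
  colnames(out) <- Y$variable_names
  attr(out, "time") <- times[j]
  out
}

#' Collapse the two progenitor levels into one reported variable
#'
#' The model tracks progenitors at two levels (PC1, PC2) but results are
#' reported for the total progenitor pool `N_PC = N_PC1 + N_PC2`. Returns
#' an ensemble with variables `N_CSC, N_PC, N_TC, N_DC`.
#'
#' @param Y A CSC-model [simulateEnsemble()] output.
#' @return An `ensembleOutput` with four variables.
#' @export
collapseProgenitors <- function(Y) {
  stopifnot(inherits(Y, "ensembleOutput"))
  need <- c("N_CSC", "N_PC1", "N_PC2", "N_TC", "N_DC")
  if (!all(need %in% Y$variable_names)) {
    stop("ensemble does not contain the five CSC-model variables",
         call. = FALSE)
  }
  d <- dim(Y$values)
  out <- array(NA_real_, dim = c(d[1], d[2], 4),
               dimnames = list(NULL, NULL, c("N_CSC", "N_PC", "N_TC", "N_DC")))
  out[, , "N_CSC"] <- Y$values[, , "N_CSC"]
  out[, , "N_PC"] <- Y$values[, , "N_PC1"] + Y$values[, , "N_PC2"]
  out[, , "N_TC"] <- Y$values[, , "N_TC"]
  out[, , "N_DC"] <- Y$values[, , "N_DC"]
  structure(list(grid = Y$grid,
                 variable_names = c("N_CSC", "N_PC", "N_TC", "N_DC"),
                 values = out,
                 success = Y$success,
                 failure_log = Y$failure_log),
            class = "ensembleOutput")
}

#' Persist an ensemble as wide CSV files
#'
#' Writes one CSV per output variable (rows = samples, columns = grid
#' times) plus a JSON metadata sidecar (grid, variable names, success
#' flags).
#'
#' @param Y An [simulateEnsemble()] output.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeEnsemble <- function(Y, dir) {
  stopifnot(inherits(Y, "ensembleOutput"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (v in Y$variable_names) {
    f <- file.path(dir, paste0("Y_", v, ".csv"))
    m <- Y$values[, , v]
    colnames(m) <- sprintf("t_%g", Y$grid$times)
    utils::write.csv(m, f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- file.path(dir, "ensemble.json")
  jsonlite::write_json(list(t_ini = Y$grid$t_ini, t_end = Y$grid$t_end,
                            times = Y$grid$times,
                            variables = Y$variable_names,
                            success = Y$success),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}
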